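test_that("circular mean and SD match closed forms", {
  cs <- circular_mean_sd(c(50, 60))
  expect_equal(cs$mean, 55)
  expect_equal(cs$sd, sqrt(-2 * log(cos(5 * pi / 180))) * 180 / pi,
               tolerance = 1e-9)

  expect_equal(circular_mean_sd(c(350, 10))$mean, 0, tolerance = 1e-9)

  deg <- circular_mean_sd(c(90, 90, 90))
  expect_equal(deg$mean, 90)
  expect_equal(deg$sd, 0)

  anti <- circular_mean_sd(c(0, 180))
  expect_true(anti$undefined)
  expect_true(is.na(anti$mean))
})

test_that("circular statistics respect rotation and wrap invariances", {
  set.seed(40)
  x <- stats::runif(50, 0, 180)
  a <- circular_mean_sd(x)
  b <- circular_mean_sd(x + 360)
  expect_equal(a$mean, b$mean, tolerance = 1e-9)
  expect_equal(a$sd, b$sd, tolerance = 1e-9)
  expect_equal(circular_mean_sd(rep(137.5, 9))$mean, 137.5)
})

test_that("one-way ANOVA matches the standard decomposition", {
  id <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(id$F, 0)
  expect_equal(id$p, 1)

  # hand decomposition: SSB = 400 (df 2), SSW = 1.5 (df 3) -> F = 400
  a <- anova_oneway(list(c(1, 2), c(11, 12), c(21, 22)))
  expect_equal(a$ss_between, 400)
  expect_equal(a$ss_within, 1.5)
  expect_equal(a$F, 400)
  expect_equal(a$p, stats::pf(400, 2, 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(a$significant)

  # cross-check against the standard fitter
  set.seed(9)
  g1 <- stats::rnorm(8); g2 <- stats::rnorm(10, 0.5); g3 <- stats::rnorm(6, 1)
  mine <- anova_oneway(list(g1, g2, g3))
  ref <- stats::oneway.test(c(g1, g2, g3) ~ factor(rep(1:3, c(8, 10, 6))),
                            var.equal = TRUE)
  expect_equal(mine$F, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)

  # F equals squared pooled t for two groups
  t2 <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(anova_oneway(list(g1, g2))$F, unname(t2$statistic)^2,
               tolerance = 1e-9)
})

test_that("ANOVA p is invariant under shifts and group relabeling", {
  set.seed(10)
  gr <- list(stats::rnorm(5), stats::rnorm(7, 1), stats::rnorm(6, 2))
  p0 <- anova_oneway(gr)$p
  expect_equal(anova_oneway(lapply(gr, `+`, 100))$p, p0, tolerance = 1e-9)
  expect_equal(anova_oneway(rev(gr))$p, p0, tolerance = 1e-9)
  expect_error(anova_oneway(list(1:3)), "2 groups")
  expect_error(anova_oneway(list(1:3, 5)), "2 values")
})

test_that("boxplot statistics follow the quartile convention", {
  x <- c(1, 2, 3, 4, 100)
  b <- boxplot_stats(x)
  expect_equal(unname(b[c("min", "median", "max")]), c(1, 3, 100))
  expect_equal(unname(b["q25"]), unname(stats::quantile(x, 0.25)))
})

analysed_stack <- function(seed, n_branches = 40) {
  g <- simulate_network(network_config(n_target_branches = n_branches,
                                       seed = seed))
  list(graph = g, branches = extract_branches(g),
       angles = furcation_angles(g),
       complexity = network_complexity(g),
       small_world = NULL)
}

test_that("make_report writes a complete deterministic bundle", {
  stacks <- list(s1 = analysed_stack(1), s2 = analysed_stack(2))
  d1 <- withr::local_tempdir()
  rep1 <- make_report(stacks, d1)
  expect_identical(nrow(rep1), 2L)
  expect_true(all(file.exists(file.path(d1, c("report.csv",
                                              "angles_alpha.csv",
                                              "angles_beta.csv",
                                              "summary.json")))))
  expect_false(any(is.na(rep1$GE)))

  d2 <- withr::local_tempdir()
  make_report(stacks, d2)
  expect_identical(readLines(file.path(d1, "report.csv")),
                   readLines(file.path(d2, "report.csv")))
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))

  js <- jsonlite::read_json(file.path(d1, "summary.json"),
                            simplifyVector = TRUE)
  expect_identical(js$n_stacks, 2L)
  expect_true(js$assortativity$n_defined <= 2)
})

test_that("single stack smoke and indeterminate verdict propagation", {
  st <- analysed_stack(3)
  st$small_world <- small_world_test(
    graph_from_edges(rbind(c(1, 2), c(2, 3)), n_nodes = 3))
  out <- withr::local_tempdir()
  rep <- make_report(list(st), out)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$small_world, "indeterminate")
})
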