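#' Assemble the per-stack analysis report
#'
#' Takes the analysed stacks (each a list with the stack's graph, branch
#' set, angles, complexity metrics and small-world result, as produced by
#' [run_pipeline()] or assembled by hand) and writes the deterministic
#' report bundle: a per-stack metric CSV, alpha/beta angle CSVs, a JSON
#' summary (branch-length statistics, circular angle statistics, ANOVA
#' across stacks, assortativity bookkeeping, small-world verdicts) and,
#' optionally, diagnostic plots.
#'
#' @param stacks named list; each element needs fields `branches`
#'   (`branch_set`), `angles` (`furcation_angles`), `complexity`
#'   (`network_complexity`) and `small_world` (`small_world_test` or NULL).
#' @param out_dir output directory (created if missing).
#' @param plots also write PNG figures (branch-length histogram, angle
#'   boxplots, betweenness histograms); default `FALSE` so headless runs
#'   never depend on a graphics device.
#' @return Invisibly, the per-stack summary data frame (also written to
#'   `report.csv`).
#' @export
make_report <- function(stacks, out_dir, plots = FALSE) {
  if (length(stacks) < 1) stopf("no stacks to report")
  if (is.null(names(stacks)) || any(!nzchar(names(stacks)))) {
    names(stacks) <- sprintf("stack%02d", seq_along(stacks))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  row_for <- function(name, st) {
    cx <- st$complexity
    bs <- branch_stats(st$branches)
    sw <- st$small_world
    alpha <- st$angles$angle[st$angles$class == "alpha"]
    beta <- st$angles$angle[st$angles$class == "beta"]
    data.frame(
      stack = name,
      n_nodes = cx$n_nodes, n_edges = cx$n_edges,
      n_branches = bs$n, branch_mean = bs$mean, branch_median = bs$median,
      n_alpha = length(alpha), n_beta = length(beta),
      alpha_mean = if (length(alpha)) mean(alpha) else NA_real_,
      beta_mean = if (length(beta)) mean(beta) else NA_real_,
      GE = cx$global_efficiency,
      LE = cx$local_efficiency$mean,
      CPL = cx$characteristic_path_length$cpl,
      mean_degree = mean(cx$degree),
      assortativity = cx$assortativity,
      GE_rand = if (is.null(sw)) NA_real_ else sw$GE_rand_mean,
      GE_latt = if (is.null(sw)) NA_real_ else sw$GE_latt_mean,
      LE_rand = if (is.null(sw)) NA_real_ else sw$LE_rand_mean,
      LE_latt = if (is.null(sw)) NA_real_ else sw$LE_latt_mean,
      small_world = if (is.null(sw)) NA_character_
                    else as.character(sw$small_world),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, Map(row_for, names(stacks), stacks))
  utils::write.csv(report, file.path(out_dir, "report.csv"),
                   row.names = FALSE)

  angle_rows <- function(cls) {
    do.call(rbind, Map(function(name, st) {
      a <- st$angles[st$angles$class == cls, , drop = FALSE]
      if (nrow(a) == 0) return(NULL)
      data.frame(stack = name, node = a$node, angle = a$angle,
                 stringsAsFactors = FALSE)
    }, names(stacks), stacks))
  }
  alpha_df <- angle_rows("alpha")
  beta_df <- angle_rows("beta")
  utils::write.csv(alpha_df, file.path(out_dir, "angles_alpha.csv"),
                   row.names = FALSE)
  utils::write.csv(beta_df, file.path(out_dir, "angles_beta.csv"),
                   row.names = FALSE)

  all_len <- unlist(lapply(stacks, function(st) st$branches$length))
  anova_for <- function(df) {
    if (is.null(df)) return(NULL)
    groups <- split(df$angle, df$stack)
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) < 2) return(NULL)
    a <- anova_oneway(groups)
    a[c("F", "p", "df_between", "df_within", "significant")]
  }
  neg_assort <- sum(report$assortativity < 0, na.rm = TRUE)
  summary <- list(
    n_stacks = length(stacks),
    branch_lengths = list(n = length(all_len), mean = mean(all_len),
                          median = stats::median(all_len)),
    alpha = if (!is.null(alpha_df)) circular_mean_sd(alpha_df$angle),
    beta = if (!is.null(beta_df)) circular_mean_sd(beta_df$angle),
    anova_alpha = anova_for(alpha_df),
    anova_beta = anova_for(beta_df),
    assortativity = list(
      n_negative = neg_assort,
      n_defined = sum(!is.na(report$assortativity)),
      min = suppressWarnings(min(report$assortativity, na.rm = TRUE)),
      max = suppressWarnings(max(report$assortativity, na.rm = TRUE))),
    small_world = as.list(table(report$small_world, useNA = "no")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  if (plots) {
    report_plots(stacks, report, out_dir)
  }
  invisible(report)
}

# Diagnostic figures: branch-length histogram, per-stack angle boxplots,
# per-stack betweenness histograms.
report_plots <- function(stacks, report, out_dir) {
  safe_png <- function(file, code) {
    ok <- tryCatch({
      grDevices::png(file, width = 900, height = 600)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      warnf("no PNG device available; skipping %s", basename(file))
      return(invisible(NULL))
    }
    on.exit(grDevices::dev.off())
    force(code)
  }
  all_len <- unlist(lapply(stacks, function(st) st$branches$length))
  safe_png(file.path(out_dir, "branch_length_hist.png"), {
    graphics::hist(all_len, breaks = seq(0, max(300, ceiling(max(all_len) / 25) * 25), 25),
                   main = "Branch lengths", xlab = "length (um)",
                   col = "grey80")
  })
  for (cls in c("alpha", "beta")) {
    groups <- lapply(stacks, function(st)
      st$angles$angle[st$angles$class == cls])
    groups <- groups[lengths(groups) > 0]
    if (length(groups) == 0) next
    safe_png(file.path(out_dir, sprintf("angles_%s_boxplot.png", cls)), {
      graphics::boxplot(groups, range = 0, las = 2,
                        main = sprintf("%s angles per stack", cls),
                        ylab = "angle (degrees)")
    })
  }
  safe_png(file.path(out_dir, "betweenness_hist.png"), {
    k <- length(stacks)
    nc <- ceiling(sqrt(k))
    graphics::par(mfrow = c(ceiling(k / nc), nc), mar = c(2, 2, 2, 0.5))
    for (name in names(stacks)) {
      h <- stacks[[name]]$complexity$betweenness$histogram
      graphics::barplot(h$count, names.arg = sprintf("%.1f", h$lower),
                        main = name, border = NA)
    }
  })
  invisible(NULL)
}
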