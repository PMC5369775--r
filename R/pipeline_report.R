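# End-to-end orchestration and reporting: cluster -> risk table -> trend ->
# composition-annotated cluster x outcome heat map, with all artifacts
# written to disk and a run manifest.

#' Per-cluster risk-factor composition
#'
#' Proportion of subjects in each cluster carrying each risk factor.
#'
#' @param partition `partition` object.
#' @param factors risk_factor_matrix aligned with the partition.
#' @return `K x J` matrix of proportions in `[0, 1]`.
#' @export
cluster_composition <- function(partition, factors) {
  stopifnot(inherits(partition, "partition"),
            length(partition$labels) == nrow(factors))
  t(vapply(seq_len(partition$K), function(c_) {
    colMeans(factors[partition$labels == c_, , drop = FALSE])
  }, numeric(ncol(factors))))
}

# Order clusters by size descending, ties by cluster index.
cluster_display_order <- function(partition) {
  sizes <- tabulate(partition$labels, nbins = partition$K)
  order(-sizes, seq_len(partition$K))
}

#' Render the cluster x outcome heat map
#'
#' Left panel: per-cluster risk-factor composition as black boxes whose area
#' is proportional to the within-cluster prevalence of the factor. Right
#' panel: per-outcome risk-ratio cells, coloured on a symmetric log(RR)
#' scale (clipped at 1/30 and 30, anchored white at RR = 1) only where the
#' cell is significant under the selected mode; non-significant cells are
#' left uncoloured. Clusters are ordered by size, descending.
#'
#' @param risk_table data.frame from [compute_risk_table()].
#' @param composition matrix from [cluster_composition()].
#' @param partition the `partition` the table was computed from.
#' @param file output file; the device is chosen from the extension
#'   (`.svg` or `.pdf`). `NULL` returns the plot without writing.
#' @param significance `"nominal"` (p < alpha) or `"bonferroni"`.
#' @return the ggplot object, invisibly; writes `file` when given.
#' @export
render_heatmap <- function(risk_table, composition, partition, file = NULL,
                           significance = c("nominal", "bonferroni")) {
  significance <- match.arg(significance)
  if (!setequal(unique(risk_table$cluster), seq_len(nrow(composition))))
    stop_("render_heatmap: risk table and composition cover different clusters")
  ord <- cluster_display_order(partition)
  sizes <- tabulate(partition$labels, nbins = partition$K)
  row_lab <- sprintf("C%d (n = %d)", seq_along(ord), sizes[ord])
  row_of <- match(risk_table$cluster, ord)

  flag <- if (significance == "nominal") risk_table$significant_nominal
          else risk_table$significant_bonferroni
  outs <- unique(risk_table$outcome)
  rr_df <- data.frame(
    row = factor(row_lab[row_of], levels = rev(row_lab)),
    col = factor(risk_table$outcome, levels = outs),
    fill = ifelse(flag, pmax(pmin(log(pmax(risk_table$rr, 1 / 30)), log(30)),
                             log(1 / 30)), NA_real_),
    label = format_rr(risk_table$rr))

  comp <- composition[ord, , drop = FALSE]
  comp_df <- data.frame(
    row = factor(rep(row_lab, ncol(comp)), levels = rev(row_lab)),
    col = factor(rep(colnames(comp), each = nrow(comp)),
                 levels = colnames(comp)),
    prop = as.vector(comp))
  comp_df$side <- sqrt(comp_df$prop)  # area proportional to prevalence

  p_comp <- ggplot2::ggplot(comp_df, ggplot2::aes(x = col, y = row)) +
    ggplot2::geom_tile(fill = "white", colour = "grey80") +
    ggplot2::geom_tile(ggplot2::aes(width = side, height = side),
                       fill = "black") +
    ggplot2::labs(x = "risk factor", y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1),
                   panel.grid = ggplot2::element_blank())

  p_rr <- ggplot2::ggplot(rr_df, ggplot2::aes(x = col, y = row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = fill), colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = label), size = 2.4) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(log(1 / 30), log(30)),
                                  na.value = "grey95",
                                  name = "log RR") +
    ggplot2::labs(x = sprintf("outcome (coloured if significant, %s)",
                              significance), y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1),
                   axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())

  plt <- structure(list(composition = p_comp, risks = p_rr),
                   class = "riskclust_heatmap")
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    w <- 4 + 0.28 * (ncol(comp) + length(outs))
    h <- 2 + 0.22 * length(row_lab)
    if (ext == "svg") grDevices::svg(file, width = w, height = h)
    else if (ext == "pdf") grDevices::pdf(file, width = w, height = h)
    else stop_("render_heatmap: unsupported extension '", ext, "'")
    on.exit(grDevices::dev.off())
    print(plt)
  }
  invisible(plt)
}

#' @export
print.riskclust_heatmap <- function(x, ...) {
  sq <- function(g) suppressWarnings(ggplot2::ggplotGrob(g))
  g1 <- sq(x$composition)
  g2 <- sq(x$risks)
  g1$heights <- grid::unit.pmax(g1$heights, g2$heights)
  g2$heights <- g1$heights
  grid::grid.newpage()
  lay <- grid::grid.layout(1, 2, widths = grid::unit(c(1, 1.15), "null"))
  grid::pushViewport(grid::viewport(layout = lay))
  grid::pushViewport(grid::viewport(layout.pos.col = 1))
  grid::grid.draw(g1)
  grid::popViewport()
  grid::pushViewport(grid::viewport(layout.pos.col = 2))
  grid::grid.draw(g2)
  grid::popViewport(2)
  invisible(x)
}

#' Run the full risk-cluster analysis pipeline
#'
#' Stages in order: cluster the risk-factor profiles, compute the cluster x
#' outcome risk table, fit the logistic trend of the primary outcome on the
#' risk-factor count, and render the heat map. When `outdir` is given, the
#' partition, risk table, trend fit, per-count RR curve, heat map and a run
#' manifest (seed, settings, md5 checksums of every artifact) are written
#' there.
#'
#' @param factors risk_factor_matrix (or use `cohort_path` + `schema`).
#' @param outcomes outcome_matrix.
#' @param cohort_path,schema alternative input: a cohort CSV read with
#'   [read_cohort()].
#' @param ref reference_rates.
#' @param prior prior_spec for the clustering.
#' @param settings search_settings (its `seed` drives all randomness).
#' @param trend_outcome outcome column for the trend model.
#' @param conf,alpha inference settings for the risk table.
#' @param significance heat-map significance mode.
#' @param outdir output directory, or NULL for no files.
#' @return list with `partition`, `risk_table`, `trend`, `rr_by_count`,
#'   `composition`, `summary`, and `files` (named paths, when written).
#' @export
run_pipeline <- function(factors = NULL, outcomes = NULL,
                         cohort_path = NULL, schema = NULL,
                         ref = predo_reference_rates(),
                         prior = prior_spec(),
                         settings = search_settings(),
                         trend_outcome = "pe",
                         conf = 0.95, alpha = 0.05,
                         significance = "nominal",
                         outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  if (!is.null(cohort_path)) {
    co <- stage("read", read_cohort(cohort_path, schema))
    factors <- co$factors
    outcomes <- co$outcomes
  }
  check_aligned(factors, outcomes)
  viol <- validate_outcome_hierarchy(outcomes)
  if (nrow(viol))
    stop_("pipeline stage 'validate' failed: ", nrow(viol),
          " outcome-hierarchy violation(s)")

  sp <- stage("cluster", search_partition(factors, prior, settings))
  risks <- stage("risks", compute_risk_table(sp$partition, outcomes, ref,
                                             conf = conf, alpha = alpha))
  counts <- count_risk_factors(factors)
  trend <- stage("trend",
                 fit_logistic_trend(counts, outcomes[, trend_outcome]))
  p0 <- expand_subtype_rates(ref)
  curve <- stage("trend", rr_by_count(counts, outcomes[, trend_outcome],
                                      p0[[trend_outcome]], conf))
  comp <- cluster_composition(sp$partition, factors)

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    f <- function(x) file.path(outdir, x)
    files <- c(partition = f("partition.csv"), risks = f("risks.csv"),
               trend = f("trend.csv"), heatmap = f("heatmap.svg"),
               manifest = f("manifest.json"))
    utils::write.csv(data.frame(subject_id = rownames(factors),
                                cluster = sp$partition$labels),
                     files[["partition"]], row.names = FALSE, quote = FALSE)
    write_risk_table(risks, files[["risks"]])
    utils::write.csv(cbind(data.frame(slope = trend$slope, se = trend$se,
                                      p_value = trend$p_value,
                                      intercept = trend$intercept,
                                      converged = trend$converged)),
                     files[["trend"]], row.names = FALSE, quote = FALSE)
    stage("report", render_heatmap(risks, comp, sp$partition,
                                   files[["heatmap"]], significance))
    manifest <- list(
      seed = settings$seed, n_subjects = nrow(factors),
      K = sp$partition$K, score = sp$score,
      settings = list(n_restarts = settings$n_restarts,
                      max_sweeps = settings$max_sweeps,
                      moves = settings$moves,
                      alpha0 = prior$alpha0, beta0 = prior$beta0,
                      max_clusters = prior$max_clusters,
                      conf = conf, alpha = alpha),
      checksums = {
        art <- setdiff(names(files), "manifest")
        as.list(stats::setNames(unname(tools::md5sum(files[art])), art))
      })
    jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  list(partition = sp$partition, score = sp$score, risk_table = risks,
       trend = trend, rr_by_count = curve, composition = comp,
       summary = summarize_cohort(factors, outcomes), files = files)
}

#' Write / read a risk table CSV
#'
#' `write_risk_table()` writes the full-precision table;
#' `read_risk_table()` parses it back to an identical data.frame
#' (round-trip exact via full-precision formatting).
#'
#' @param risk_table data.frame from [compute_risk_table()].
#' @param path CSV path.
#' @return `path` / the parsed data.frame.
#' @export
write_risk_table <- function(risk_table, path) {
  tab <- risk_table
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_risk_table
#' @export
read_risk_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$significant_nominal <- as.logical(tab$significant_nominal)
  tab$significant_bonferroni <- as.logical(tab$significant_bonferroni)
  tab
}
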