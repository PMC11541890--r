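#' Screen a whole panel of samples
#'
#' Runs the full pipeline (preprocess both scans, detect peaks, apply the
#' R1/R2 positivity rule, assign groups, flag interferents) over every
#' sample of a panel and tabulates the calls. When the panel carries truth
#' labels (as the synthetic fixture does), the summary reports percent
#' agreement of the positive/negative calls.
#'
#' @param panel An `sc_panel` from [make_fixture_46()], or a plain list of
#'   samples, each a list with `anodic`, `cathodic` (and optionally `id`,
#'   `truth`).
#' @param config A [screen_config()].
#' @return Object of class `panel_screening`: `results` (one row per
#'   sample) and `summary` (list: `n`, `n_positive`, `n_negative`,
#'   `agreement_pct` when truth labels exist).
#' @export
screen_panel <- function(panel, config = screen_config()) {
  samples <- if (inherits(panel, "sc_panel")) panel$samples else panel
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    res <- screen_sample(s$anodic, s$cathodic, config)
    data.frame(
      sample = if (is.null(s$id)) i else s$id,
      positive = res$positive,
      r1_found = res$r1_found,
      r2_found = res$r2_found,
      group = res$assigned_group,
      anodic_count = res$anodic_count,
      flags = paste(res$interferent_flags, collapse = ","),
      truth_positive = if (is.null(s$truth)) NA else s$truth$positive,
      truth_group = if (is.null(s$truth)) NA_character_ else s$truth$group
    )
  })
  results <- do.call(rbind, rows)
  summary <- list(n = nrow(results),
                  n_positive = sum(results$positive),
                  n_negative = sum(!results$positive))
  if (!all(is.na(results$truth_positive))) {
    summary$agreement_pct <-
      100 * mean(results$positive == results$truth_positive)
  }
  structure(list(results = results, summary = summary),
            class = "panel_screening")
}

#' @export
print.panel_screening <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Panel screening: %d samples, %d positive / %d negative\n",
              s$n, s$n_positive, s$n_negative))
  if (!is.null(s$agreement_pct)) {
    cat(sprintf("  agreement with truth labels: %.1f%%\n", s$agreement_pct))
  }
  invisible(x)
}

#' Write a panel fixture to disk as CSV traces plus a manifest
#'
#' One pair of trace files per sample plus `manifest.tsv` with the truth
#' labels and relative trace paths; the layout [read_panel()] reads back.
#'
#' @param panel An `sc_panel`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "sc_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- panel$manifest
  man$anodic_path <- sprintf("sample%02d_anodic.csv", man$sample)
  man$cathodic_path <- sprintf("sample%02d_cathodic.csv", man$sample)
  for (i in seq_along(panel$samples)) {
    s <- panel$samples[[i]]
    write_voltammogram(s$anodic, file.path(dir, man$anodic_path[i]),
                       sidecar = FALSE)
    write_voltammogram(s$cathodic, file.path(dir, man$cathodic_path[i]),
                       sidecar = FALSE)
  }
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a panel written by [write_panel()]
#'
#' @param manifest Path to a `manifest.tsv`.
#' @return A list of samples suitable for [screen_panel()].
#' @export
read_panel <- function(manifest) {
  man <- utils::read.table(manifest, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  base <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    list(id = man$sample[i],
         anodic = read_voltammogram(file.path(base, man$anodic_path[i])),
         cathodic = read_voltammogram(file.path(base, man$cathodic_path[i])),
         truth = if ("truth_positive" %in% names(man)) {
           list(positive = man$truth_positive[i],
                group = if ("truth_group" %in% names(man))
                  man$truth_group[i] else NA_character_)
         })
  })
}
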