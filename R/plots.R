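# Report figures: correlation heatmap with non-significant cells crossed
# out, per-group bootstrap-distribution density panels (ridgeline-style),
# box-plot panels, and the synoptic trend table.

utils::globalVariables(c("comparison", "scope", "median_wincorr", "value",
                         "group", "label"))

save_plot <- function(p, path_stem, width, height) {
  png_file <- paste0(path_stem, ".png")
  grDevices::png(png_file, width = width * 96, height = height * 96, res = 96)
  print(p)
  grDevices::dev.off()
  svg_file <- paste0(path_stem, ".svg")
  ok <- tryCatch({
    grDevices::svg(svg_file, width = width, height = height)
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) FALSE)
  c(png_file, if (isTRUE(ok)) svg_file)
}

ensemble_long <- function(ens) {
  d <- dimnames(ens)
  out <- expand.grid(replicate = seq_len(dim(ens)[1]),
                     comparison = d[[2]], group = d[[3]],
                     stringsAsFactors = FALSE)
  out$value <- as.vector(unclass(ens))
  out[out$group %in% sap_groups() & !is.na(out$value), ]
}

#' Render report figures and tables from a result bundle
#'
#' Writes, under `outdir`: `correlation_heatmap` (median WINcorr per
#' comparison x scope; non-significant cells at 0.05 carry an X marker),
#' `bootstrap_ridgelines` (within-group bootstrap densities per
#' comparison), `bootstrap_boxplots`, and `synoptic_trends` (the trend
#' classification as CSV and as a labelled tile figure; unsupported
#' umbrella trends show "---"). Figures are emitted as PNG, and as SVG when
#' the device is available. File names are deterministic given `outdir`.
#'
#' @param bundle A `result_bundle`.
#' @param outdir Output directory (created if missing).
#' @return Character vector of written files, invisibly.
#' @export
render_reports <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  s <- bundle$summary
  s$comparison <- factor(s$comparison, levels = comparison_names())
  s$scope <- factor(s$scope, levels = analysis_scopes())

  heat <- ggplot2::ggplot(s, ggplot2::aes(scope, comparison,
                                          fill = median_wincorr)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_point(data = s[s$perm_p >= 0.05, , drop = FALSE],
                        shape = 4, size = 5, stroke = 1.2) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1),
                                  name = "median WINcorr") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Median Winsorized correlations with the alpha index",
                  subtitle = "X: zero correlation not rejected (permutation test, 0.05)") +
    ggplot2::theme_minimal()
  files <- c(files, save_plot(heat, file.path(outdir, "correlation_heatmap"), 7, 8))

  if (!is.null(bundle$ensemble)) {
    el <- ensemble_long(bundle$ensemble)
    el$comparison <- factor(el$comparison, levels = comparison_names())
    el$group <- factor(el$group, levels = sap_groups())
    ridge <- ggplot2::ggplot(el, ggplot2::aes(value, fill = group)) +
      ggplot2::geom_density(alpha = 0.55, color = NA) +
      ggplot2::facet_wrap(~comparison, scales = "free_y", ncol = 2) +
      ggplot2::labs(x = "WINcorr", y = NULL,
                    title = "Bootstrap distributions of WINcorr by SAP group") +
      ggplot2::theme_minimal()
    files <- c(files, save_plot(ridge, file.path(outdir, "bootstrap_ridgelines"),
                                8, 12))
    box <- ggplot2::ggplot(el, ggplot2::aes(group, value, fill = group)) +
      ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
      ggplot2::facet_wrap(~comparison, ncol = 4) +
      ggplot2::labs(x = NULL, y = "WINcorr",
                    title = "Within-group bootstrap WINcorr distributions") +
      ggplot2::theme_minimal()
    files <- c(files, save_plot(box, file.path(outdir, "bootstrap_boxplots"),
                                10, 9))
  } else {
    warning("no ensemble in bundle: ridgeline/box panels skipped")
  }

  tr <- bundle$trends
  syn_csv <- file.path(outdir, "synoptic_trends.csv")
  syn <- tr[c("comparison", "monotonic", "nt_end", "ht_end", "umbrella",
              "strongest", "band")]
  syn$umbrella <- c(concave = "\u2229", convex = "\u222a",
                    none = "---")[syn$umbrella]
  utils::write.csv(syn, syn_csv, row.names = FALSE, quote = FALSE)
  files <- c(files, syn_csv)

  syn_long <- data.frame(
    comparison = factor(rep(syn$comparison, 3), levels = rev(comparison_names())),
    column = factor(rep(c("monotonic", "umbrella", "strongest"),
                        each = nrow(syn)),
                    levels = c("monotonic", "umbrella", "strongest")),
    label = c(paste0(syn$monotonic, " (", syn$nt_end, "\u2192", syn$ht_end, ")"),
              syn$umbrella, paste0(syn$strongest, " [", syn$band, "]")),
    stringsAsFactors = FALSE)
  synp <- ggplot2::ggplot(syn_long, ggplot2::aes(column, comparison)) +
    ggplot2::geom_tile(fill = "grey95", color = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = label), size = 3) +
    ggplot2::labs(x = NULL, y = NULL, title = "Synoptic trend classification") +
    ggplot2::theme_minimal()
  files <- c(files, save_plot(synp, file.path(outdir, "synoptic_trends"), 8, 6))
  invisible(files)
}
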