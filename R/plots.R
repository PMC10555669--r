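## Diagnostic panels: effect-direction scatter, EAF-vs-reference scatter,
## expected-vs-reported scatter with identity and fitted lines, and the P-Z
## scatter. One file per panel; panels without data are written as labelled
## placeholders so a report always yields the same set of files.

.qcDevice <- function() {
  caps <- grDevices::dev.capabilities
  if (isTRUE(unname(capabilities("png")))) "png" else "pdf"
}

.savePanel <- function(plot, path_stem) {
  dev <- .qcDevice()
  path <- paste0(path_stem, ".", dev)
  ggplot2::ggsave(path, plot, device = dev, width = 5, height = 4.2,
                  dpi = 150, units = "in")
  path
}

.placeholderPanel <- function(title, note) {
  ggplot2::ggplot() +
    ggplot2::annotate("text", x = 0, y = 0, label = note, size = 4) +
    ggplot2::labs(title = title) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(size = 11))
}

.levelScale <- function() {
  ggplot2::scale_colour_manual(
    values = c(none = "grey55", moderate = "#E69F00", high = "#D55E00"),
    name = "conflict")
}

#' Render the four diagnostic panels of a QC report
#'
#' Writes one file per panel into \code{outdir}: \code{direction} (test vs
#' reference z-scores, conflicts coloured by level), \code{eaf} (test vs
#' reference effect allele frequencies), \code{expected_vs_reported}
#' (with identity and fitted lines) and \code{pz} (beta/SE z-scores vs
#' P-value z-scores). Panels without data are written as placeholders.
#' PNG is used when the R build supports it, PDF otherwise.
#'
#' @param report a \code{\link{QcReport-class}}.
#' @param outdir output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
renderPlots <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  pd <- report@plotData
  out <- character(0)

  p <- if (!is.null(pd$direction) && nrow(pd$direction)) {
    ggplot2::ggplot(pd$direction,
                    ggplot2::aes(x = .data$z_ref, y = .data$z_test,
                                 colour = .data$level)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 3) +
      ggplot2::geom_vline(xintercept = 0, linetype = 3) +
      ggplot2::geom_point(alpha = 0.8) +
      .levelScale() +
      ggplot2::labs(title = "Effect direction vs top hits",
                    x = "reference z-score", y = "test z-score")
  } else .placeholderPanel("Effect direction vs top hits", "not assessable")
  out["direction"] <- .savePanel(p, file.path(outdir, "direction"))

  p <- if (!is.null(pd$eaf) && nrow(pd$eaf)) {
    ggplot2::ggplot(pd$eaf,
                    ggplot2::aes(x = .data$eaf_ref, y = .data$eaf_test,
                                 colour = .data$level)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
      ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
      ggplot2::geom_vline(xintercept = 0.5, linetype = 3) +
      ggplot2::geom_point(alpha = 0.8) +
      .levelScale() +
      ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
      ggplot2::labs(title = "Effect allele frequency vs top hits",
                    x = "reference EAF", y = "test EAF")
  } else .placeholderPanel("Effect allele frequency vs top hits",
                           "not assessable")
  out["eaf"] <- .savePanel(p, file.path(outdir, "eaf"))

  p <- if (!is.null(pd$expected) && nrow(pd$expected)) {
    sl <- report@slope
    ggplot2::ggplot(pd$expected,
                    ggplot2::aes(x = .data$reported, y = .data$expected)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
      ggplot2::geom_point(alpha = 0.6, colour = "grey30") +
      ggplot2::geom_abline(slope = sl$slope, intercept = sl$intercept,
                           colour = "#0072B2") +
      ggplot2::labs(
        title = sprintf("Expected vs reported effect size (slope %.2f)",
                        sl$slope),
        x = "reported effect size", y = "expected effect size")
  } else .placeholderPanel("Expected vs reported effect size",
                           "not assessable")
  out["expected_vs_reported"] <- .savePanel(
    p, file.path(outdir, "expected_vs_reported"))

  p <- if (!is.null(pd$pz) && nrow(pd$pz)) {
    ggplot2::ggplot(pd$pz, ggplot2::aes(x = .data$z_p, y = .data$z_b)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
      ggplot2::geom_point(alpha = 0.6, colour = "grey30") +
      ggplot2::labs(
        title = sprintf("P-Z consistency (r = %.4f)", report@pz$r),
        x = "z from reported P-value", y = "z from beta / SE")
  } else .placeholderPanel("P-Z consistency", "not assessable")
  out["pz"] <- .savePanel(p, file.path(outdir, "pz"))

  out
}
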