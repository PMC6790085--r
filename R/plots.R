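#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-base cleavage signal around a region
#'
#' Strand-resolved cut counts over a genomic window, with optional footprint
#' intervals overlaid: the visual signature of a footprint is a plus-strand
#' peak upstream, a depleted interior and a minus-strand peak downstream.
#'
#' @param profile A `cut_profile`.
#' @param chrom,start,end Window to draw (0-based half-open).
#' @param footprints Optional interval tibble to overlay.
#' @return A ggplot object.
#' @export
plot_cut_profile <- function(profile, chrom, start, end, footprints = NULL) {
  chv <- profile$chroms[[chrom]]
  stopifnot(!is.null(chv), start >= 0, end <= length(chv$plus))
  idx <- (start + 1L):end
  df <- tibble::tibble(
    pos = rep(start:(end - 1L), 2),
    cuts = c(chv$plus[idx], -chv$minus[idx]),
    strand = rep(c("plus", "minus"), each = length(idx))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$cuts,
                                        fill = .data$strand)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(plus = "#2166ac", minus = "#b2182b")) +
    ggplot2::labs(x = paste0(chrom, " position"), y = "cuts (+ up, - down)") +
    ggplot2::theme_minimal()
  if (!is.null(footprints)) {
    fp <- footprints[footprints$chrom == chrom & footprints$end > start &
                       footprints$start < end, ]
    if (nrow(fp) > 0) {
      p <- p + ggplot2::annotate("rect", xmin = fp$start, xmax = fp$end,
                                 ymin = -Inf, ymax = Inf, alpha = 0.15,
                                 fill = "grey30")
    }
  }
  p
}

#' @export
autoplot.perm_overlap <- function(object, ...) {
  if (is.null(object$profile)) {
    stop("no local z profile: rerun with shift_window > 0", call. = FALSE)
  }
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$shift, y = .data$z)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "shift (bp)", y = "local z-score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tss_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid / 1000, y = .data$density)) +
    ggplot2::geom_col(width = diff(object$bin_start[1:2]) / 1000) +
    ggplot2::labs(x = "distance to nearest TSS (kb)",
                  y = "regions per kb per region") +
    ggplot2::theme_minimal()
}

#' Pie-style feature distribution plot
#' @param dist Output of [feature_distribution()].
#' @return A ggplot object.
#' @export
plot_feature_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = "", y = .data$fraction,
                                     fill = .data$feature)) +
    ggplot2::geom_col(width = 1, color = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "feature")
}
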