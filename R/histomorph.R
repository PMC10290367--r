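#' Labelled histology section
#'
#' Hard-labelled 2-D section for histomorphometry: each pixel carries an
#' integer code mapped to a tissue class by the legend. Exactly one class
#' must be the background; an optional ignore class (artifacts) is
#' excluded from all accounting.
#'
#' @param label_image Integer matrix of label codes.
#' @param legend Named character vector mapping code (as name) to tissue
#'   class, e.g. `c("0" = "background", "1" = "old_bone", ...)`.
#' @param background Class treated as background; default `"background"`.
#' @param ignore Optional class excluded from accounting.
#' @param pixel_size Optional pixel edge (micrometres), metadata only.
#' @return `ovtr_section` object.
#' @export
label_section <- function(label_image, legend, background = "background",
                          ignore = NULL, pixel_size = NULL) {
  stopifnot(is.matrix(label_image), !is.null(names(legend)))
  codes <- sort(unique(as.vector(label_image)))
  known <- as.integer(names(legend))
  if (!all(codes %in% known))
    stop_ovtr(sprintf("labels without legend entry: %s",
                      paste(setdiff(codes, known), collapse = ", ")),
              "ovtr_invalid_input")
  if (sum(legend == background) != 1)
    stop("legend must contain exactly one background class")
  structure(list(label_image = label_image, legend = legend,
                 background = background, ignore = ignore,
                 pixel_size = pixel_size),
            class = "ovtr_section")
}

section_counts <- function(section) {
  lab <- as.vector(section$label_image)
  classes <- section$legend[as.character(lab)]
  drop <- classes == section$background
  if (!is.null(section$ignore)) drop <- drop | classes == section$ignore
  table(factor(classes[!drop], levels = setdiff(unique(section$legend),
                                                c(section$background,
                                                  section$ignore))))
}

#' Global tissue fractions of a labelled section
#'
#' Pixels of each tissue class as a percentage of all non-background
#' pixels (the area of interest is 100%).
#'
#' @param section `ovtr_section` from [label_section()].
#' @return Named numeric vector of percentages summing to 100.
#' @export
tissue_fractions <- function(section) {
  stopifnot(inherits(section, "ovtr_section"))
  counts <- section_counts(section)
  total <- sum(counts)
  if (total == 0)
    stop_ovtr("section contains no non-background pixels",
              "ovtr_invalid_input")
  100 * as.numeric(counts) / total -> pct
  names(pct) <- names(counts)
  pct
}

#' Sectoral callus fractions (cis / endosteal / trans)
#'
#' Callus pixels in each anatomical sector as a percentage of all callus
#' pixels. Sector masks are drawn regions supplied by the analyst; they
#' must be pairwise disjoint and jointly cover every callus pixel.
#'
#' @param section `ovtr_section`.
#' @param sector_masks Named list of logical matrices (same shape as the
#'   label image), typically `cis`, `endosteal`, `trans`.
#' @param callus_classes Tissue classes counted as callus; default
#'   `c("new_bone", "callus")`.
#' @return Named numeric vector of sector percentages summing to 100, or
#'   all-`NA` when the section contains no callus (undefined marker).
#' @export
sectoral_fractions <- function(section, sector_masks,
                               callus_classes = c("new_bone", "callus")) {
  stopifnot(inherits(section, "ovtr_section"), length(sector_masks) >= 1)
  dims <- dim(section$label_image)
  for (m in sector_masks)
    if (!identical(dim(m), dims))
      stop_ovtr("sector mask shape mismatch", "ovtr_grid_mismatch")
  overlap <- Reduce(`+`, lapply(sector_masks, function(m) m * 1L))
  if (any(overlap > 1L))
    stop_ovtr("sector masks overlap", "ovtr_invalid_input")
  classes <- section$legend[as.character(as.vector(section$label_image))]
  is_callus <- matrix(classes %in% callus_classes, dims[1], dims[2])
  n_callus <- sum(is_callus)
  if (n_callus == 0) {
    out <- rep(NA_real_, length(sector_masks))
    names(out) <- names(sector_masks)
    return(out)
  }
  if (any(is_callus & overlap == 0L))
    stop_ovtr("sector masks do not cover all callus pixels",
              "ovtr_invalid_input")
  out <- vapply(sector_masks, function(m) 100 * sum(is_callus & m) / n_callus,
                numeric(1))
  out
}

#' Render a synthetic labelled section with exact class percentages
#'
#' Deterministic stand-in for a manually highlighted histology slide:
#' fills the non-background area row-major with contiguous blocks whose
#' pixel counts realise the requested class percentages exactly (largest
#' remainder rounding). Used to validate the histomorphometry accounting
#' against known ground truth.
#'
#' @param class_percents Named percentages over tissue classes (must sum
#'   to 100).
#' @param n_pixels Number of non-background pixels.
#' @param n_background Number of background pixels appended.
#' @param ncol Width of the rendered image.
#' @return `ovtr_section` whose tissue fractions equal `class_percents`.
#' @export
make_label_section <- function(class_percents, n_pixels = 10000,
                               n_background = 2000, ncol = 100) {
  stopifnot(abs(sum(class_percents) - 100) < 1e-9)
  target <- class_percents / 100 * n_pixels
  counts <- floor(target)
  short <- n_pixels - sum(counts)
  if (short > 0) {
    order_frac <- order(target - counts, decreasing = TRUE)
    counts[order_frac[seq_len(short)]] <- counts[order_frac[seq_len(short)]] + 1
  }
  codes <- seq_along(class_percents)
  pix <- c(rep(codes, times = counts), rep(0L, n_background))
  nrow <- ceiling(length(pix) / ncol)
  pad <- nrow * ncol - length(pix)
  pix <- c(pix, rep(0L, pad))
  legend <- c("0" = "background",
              stats::setNames(names(class_percents), as.character(codes)))
  label_section(matrix(as.integer(pix), nrow, ncol), legend)
}
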