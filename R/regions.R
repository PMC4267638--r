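#' Splicing consensus region definition
#'
#' Defines the modeled window around a splice site: donor (5' splice site)
#' positions -3..+8 and acceptor (3' splice site) positions -12..+2, with no
#' position 0. At the donor, negative offsets are exonic (the end of the
#' upstream exon) and positive offsets intronic; at the acceptor, negative
#' offsets are intronic and positive offsets exonic (the start of the
#' downstream exon). The nearly invariant GT (donor +1,+2) and AG
#' (acceptor -2,-1) dinucleotide positions are flagged: variants there are
#' excluded from modeling.
#'
#' @param site_kind `"donor"` or `"acceptor"`.
#' @return An object of class `"splice_region"`: a list with `site_kind`,
#'   `offsets` (signed positions, strictly increasing, no 0), `exonic_span`,
#'   `intronic_span`, `invariant` (the GT-AG offsets) and `length`.
#' @examples
#' region_definition("donor")$length    # 11
#' region_definition("acceptor")$length # 14
#' @export
region_definition <- function(site_kind = c("donor", "acceptor")) {
  site_kind <- match.arg(site_kind)
  if (site_kind == "donor") {
    offsets <- c(-3:-1, 1:8)
    exonic <- offsets < 0
    invariant <- c(1L, 2L)
  } else {
    offsets <- c(-12:-1, 1:2)
    exonic <- offsets > 0
    invariant <- c(-2L, -1L)
  }
  structure(list(
    site_kind = site_kind,
    offsets = offsets,
    exonic_span = sum(exonic),
    intronic_span = sum(!exonic),
    exonic = exonic,
    invariant = invariant,
    length = length(offsets)
  ), class = "splice_region")
}

#' Offsets modeled for variants within a consensus region
#'
#' All offsets of the region except the invariant GT-AG dinucleotide
#' positions (donor: 9 offsets; acceptor: 12 offsets).
#'
#' @param region A [region_definition()] object.
#' @return Integer vector of signed offsets.
#' @export
variant_offsets <- function(region) {
  stopifnot(inherits(region, "splice_region"))
  setdiff(region$offsets, region$invariant)
}

#' @export
print.splice_region <- function(x, ...) {
  cat(sprintf("splicing consensus region: %s, %d positions (%s..%s), GT-AG at %s\n",
              x$site_kind, x$length, min(x$offsets), max(x$offsets),
              paste(sprintf("%+d", x$invariant), collapse = ",")))
  invisible(x)
}
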