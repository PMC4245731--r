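# Physico-chemical characterization of channels: length-weighted
# Kyte-Doolittle hydropathy, Zimmerman polarity, charge census.

.chan_env <- new.env(parent = emptyenv())

#' Amino-acid property scales
#'
#' Kyte-Doolittle hydropathy, Zimmerman polarity and side-chain charge class
#' (positive: Arg, Lys, His; negative: Asp, Glu), loaded from the CSV
#' resource shipped with the package. Load-time anchor checks: hydropathy
#' runs from -4.5 (Arg) to 4.5 (Ile); the five charged residues have
#' polarities in 49.5-52.0 while all others stay below ~3.5.
#'
#' @return Data frame with columns aa (3-letter code), hydropathy, polarity,
#'   charge.
#' @export
property_scales <- function() {
  if (!is.null(.chan_env$scales)) return(.chan_env$scales)
  f <- system.file("extdata", "property_scales.csv", package = "chanatomy")
  sc <- read.csv(f, stringsAsFactors = FALSE)
  stopifnot(nrow(sc) == 20, !anyDuplicated(sc$aa))
  charged <- sc$aa %in% c("ASP", "GLU", "LYS", "ARG", "HIS")
  if (sc$hydropathy[sc$aa == "ARG"] != -4.5 ||
      sc$hydropathy[sc$aa == "ILE"] != 4.5 ||
      any(sc$hydropathy < -4.5 | sc$hydropathy > 4.5) ||
      any(sc$polarity[charged] < 49.5 | sc$polarity[charged] > 52.0) ||
      any(sc$polarity[!charged] < 0 | sc$polarity[!charged] > 3.55))
    chan_error("chanatomy_value_error", "property scale anchors violated")
  pos <- sc$aa[sc$charge == "positive"]
  neg <- sc$aa[sc$charge == "negative"]
  if (!setequal(pos, c("ARG", "LYS", "HIS")) || !setequal(neg, c("ASP", "GLU")))
    chan_error("chanatomy_value_error", "charge classes violated")
  .chan_env$scales <- sc
  sc
}

scale_lookup <- function(property = c("hydropathy", "polarity")) {
  property <- match.arg(property)
  sc <- property_scales()
  setNames(sc[[property]], sc$aa)
}

#' Length-weighted mean property of a channel lining
#'
#' `sum(w_i * v(aa_i)) / sum(w_i)`: the arc-length weights of the lining
#' residues sum up the per-residue scale values into a normalized weighted
#' mean, so the result always stays within the scale range.
#'
#' @param lining Data frame from [lining_residues()] (needs `resname`,
#'   `weight`), or a character vector of residue names (equal weights).
#' @param property `"hydropathy"` or `"polarity"`, or a named numeric vector
#'   of per-residue values.
#' @return Weighted mean in scale units.
#' @export
weighted_property <- function(lining, property = "hydropathy") {
  if (is.character(lining))
    lining <- data.frame(resname = lining, weight = 1, stringsAsFactors = FALSE)
  if (!nrow(lining))
    chan_error("chanatomy_undefined_property", "empty lining: property undefined")
  vals <- if (is.numeric(property)) property else scale_lookup(property)
  v <- vals[lining$resname]
  if (any(is.na(v)))
    chan_error("chanatomy_value_error",
               paste0("no scale value for: ",
                      paste(unique(lining$resname[is.na(v)]), collapse = ", ")))
  w <- lining$weight
  if (any(w <= 0)) chan_error("chanatomy_value_error", "weights must be > 0")
  sum(w * v) / sum(w)
}

#' Charge census of a channel lining
#'
#' Unweighted counts of lining residue instances by side-chain charge class
#' (positive: Arg, Lys, His; negative: Asp, Glu).
#'
#' @param lining Data frame with `resname`, or a character vector of residue
#'   names.
#' @return List `n_positive`, `n_negative`, `net_charge`.
#' @export
charge_census <- function(lining) {
  nm <- if (is.character(lining)) lining else lining$resname
  sc <- property_scales()
  cls <- setNames(sc$charge, sc$aa)[nm]
  np <- sum(cls == "positive", na.rm = TRUE)
  nn <- sum(cls == "negative", na.rm = TRUE)
  list(n_positive = np, n_negative = nn, net_charge = np - nn)
}

#' Whole-channel and per-layer physico-chemical summary
#'
#' @param lining Data frame from [lining_residues()] + [assign_layers()].
#' @return A `physchem_summary`: hydropathy, polarity, n_positive,
#'   n_negative, net_charge, and a `layers` data frame (internal, middle,
#'   external) with hydropathy/polarity and a `missing` flag for layers with
#'   no residues (flagged, never reported as zero).
#' @export
channel_physchem <- function(lining) {
  if (!nrow(lining))
    chan_error("chanatomy_undefined_property", "empty lining: property undefined")
  if (is.null(lining$layer))
    chan_error("chanatomy_value_error", "layers not assigned; call assign_layers()")
  layers <- c("internal", "middle", "external")
  lay <- do.call(rbind, lapply(layers, function(L) {
    sub <- lining[lining$layer == L, , drop = FALSE]
    if (!nrow(sub))
      data.frame(layer = L, hydropathy = NA_real_, polarity = NA_real_,
                 missing = TRUE)
    else
      data.frame(layer = L,
                 hydropathy = weighted_property(sub, "hydropathy"),
                 polarity = weighted_property(sub, "polarity"),
                 missing = FALSE)
  }))
  cen <- charge_census(lining)
  structure(list(
    hydropathy = weighted_property(lining, "hydropathy"),
    polarity = weighted_property(lining, "polarity"),
    n_positive = cen$n_positive,
    n_negative = cen$n_negative,
    net_charge = cen$net_charge,
    layers = lay
  ), class = "physchem_summary")
}

#' @export
print.physchem_summary <- function(x, ...) {
  cat(sprintf("<physchem> hydropathy %.2f, polarity %.1f, charges +%d/-%d (net %+d)\n",
              x$hydropathy, x$polarity, x$n_positive, x$n_negative, x$net_charge))
  invisible(x)
}
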