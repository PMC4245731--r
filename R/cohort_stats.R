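# Cohort-level statistics: occurrence/length tables per EC class,
# amino-acid frequencies and channel propensities, compartment and
# bottleneck/layer compositions.

#' Relative amino-acid frequencies of a residue multiset
#'
#' @param residues Character vector (or table) of residue names; instances,
#'   not types.
#' @return Named numeric vector summing to 1.
#' @export
residue_frequencies <- function(residues) {
  if (is.table(residues))
    residues <- rep(names(residues), as.integer(residues))
  if (!length(residues))
    chan_error("chanatomy_value_error", "empty residue multiset")
  tb <- table(residues)
  v <- as.numeric(tb) / sum(tb)
  setNames(v, names(tb))
}

#' Amino-acid propensity of a region relative to a background
#'
#' Ratio of each amino acid's frequency in the region to its frequency in
#' the background (e.g. channel walls vs whole structure). Amino acids with
#' zero background but non-zero region frequency are flagged undefined;
#' zero/zero entries are absent.
#'
#' @param region,background Frequency vectors from [residue_frequencies()].
#' @return Data frame: aa, region_freq, background_freq, propensity,
#'   undefined.
#' @export
propensity <- function(region, background) {
  aas <- sort(union(names(region), names(background)))
  rf <- ifelse(aas %in% names(region), region[aas], 0)
  bf <- ifelse(aas %in% names(background), background[aas], 0)
  keep <- rf > 0 | bf > 0
  aas <- aas[keep]; rf <- rf[keep]; bf <- bf[keep]
  data.frame(aa = aas, region_freq = unname(rf), background_freq = unname(bf),
             propensity = ifelse(bf > 0, rf / bf, NA_real_),
             undefined = bf == 0 & rf > 0,
             stringsAsFactors = FALSE)
}

# reference maximum accessible surface areas (A^2, Gly-X-Gly based,
# theoretical) for relative accessibility
.max_asa <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Relative solvent accessibility per residue
#'
#' Shrake-Rupley accessible surface area (probe 1.4 A, 960 points per atom)
#' summed per residue and divided by the residue's Gly-X-Gly reference area.
#'
#' @param s Sanitized `chan_structure` with radii.
#' @param probe Probe radius (A).
#' @param n_points Sphere sample points per atom.
#' @return Data frame: chain, resno, icode, resname, copy, asa, rel_acc.
#' @export
residue_accessibility <- function(s, probe = 1.4, n_points = 960) {
  at <- s$atoms
  asa <- cpp_sasa(atom_xyz(s), at$radius, probe, as.integer(n_points))
  key <- paste(at$copy, at$chain, at$resno, at$icode, sep = "|")
  first <- !duplicated(key)
  agg <- tapply(asa, key, sum)
  out <- at[first, c("chain", "resno", "icode", "resname", "copy")]
  out$asa <- as.numeric(agg[key[first]])
  ref <- .max_asa[out$resname]
  out$rel_acc <- ifelse(is.na(ref), NA_real_, out$asa / ref)
  rownames(out) <- NULL
  out
}

#' Classify residues into structural compartments
#'
#' Every residue becomes one of active_site, channel_wall, surface or
#' interior, with precedence active_site > channel_wall > surface/interior;
#' the surface/interior split is relative solvent accessibility >= 25%.
#'
#' @param s Sanitized `chan_structure` with radii.
#' @param channels List of decorated channels (with `$lining`).
#' @param sites List of site annotations counted as active site.
#' @param rel_threshold Surface cut on relative accessibility.
#' @return Data frame: chain, resno, icode, resname, copy, compartment.
#' @export
classify_compartments <- function(s, channels = list(), sites = list(),
                                  rel_threshold = 0.25) {
  acc <- residue_accessibility(s)
  key <- paste(acc$copy, acc$chain, acc$resno, sep = "|")
  comp <- ifelse(!is.na(acc$rel_acc) & acc$rel_acc >= rel_threshold,
                 "surface", "interior")
  wall_keys <- unique(unlist(lapply(channels, function(ch)
    if (!is.null(ch$lining) && nrow(ch$lining))
      paste(ch$lining$copy, ch$lining$chain, ch$lining$resno, sep = "|"))))
  comp[key %in% wall_keys] <- "channel_wall"
  site_keys <- unique(unlist(lapply(sites, function(st)
    unlist(lapply(sort(unique(acc$copy)), function(cp)
      paste(cp, st$residues$chain, st$residues$resno, sep = "|"))))))
  comp[key %in% site_keys] <- "active_site"
  acc$compartment <- comp
  acc[c("chain", "resno", "icode", "resname", "copy", "compartment")]
}

qualifying <- function(chs) {
  chs[!vapply(chs, `[[`, logical(1), "sub_threshold")]
}

sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_

cohort_row <- function(recs, label, thresholds = c(5, 10, 15, 20)) {
  na <- vapply(recs, `[[`, numeric(1), "n_atoms")
  lens <- lapply(recs, function(r) vapply(r$channels, `[[`, numeric(1), "length"))
  nq <- vapply(recs, function(r) length(qualifying(r$channels)), numeric(1))
  with_ch <- nq >= 1
  qlen <- unlist(lapply(recs[with_ch], function(r)
    vapply(qualifying(r$channels), `[[`, numeric(1), "length")))
  ph <- lapply(recs, function(r) {
    qs <- qualifying(r$channels)
    list(h = vapply(qs, function(ch) ch$physchem$hydropathy %||% NA_real_, numeric(1)),
         p = vapply(qs, function(ch) ch$physchem$polarity %||% NA_real_, numeric(1)))
  })
  hyd <- unlist(lapply(ph, `[[`, "h"))
  pol <- unlist(lapply(ph, `[[`, "p"))
  cnt <- vapply(thresholds, function(thr)
    sum(vapply(lens, function(L) any(L >= thr), logical(1))), numeric(1))
  data.frame(
    ec_class = label,
    n_enzymes = length(recs),
    Na = mean(na, na.rm = TRUE),
    P = 100 * mean(with_ch),
    M = if (any(with_ch)) median(nq[with_ch]) else NA_real_,
    M_mean = if (any(with_ch)) mean(nq[with_ch]) else NA_real_,
    L = if (length(qlen)) median(qlen) else NA_real_,
    L_mean = if (length(qlen)) mean(qlen) else NA_real_,
    n_ge5 = cnt[1], n_ge10 = cnt[2], n_ge15 = cnt[3], n_ge20 = cnt[4],
    hydropathy = if (length(hyd)) mean(hyd, na.rm = TRUE) else NA_real_,
    hydropathy_sem = sem(hyd[!is.na(hyd)]),
    polarity = if (length(pol)) mean(pol, na.rm = TRUE) else NA_real_,
    polarity_sem = sem(pol[!is.na(pol)]),
    stringsAsFactors = FALSE)
}

#' Summarize a cohort of enzyme records into per-class tables
#'
#' Produces, per EC class and for all records pooled: mean atom count (Na),
#' percentage of enzymes with at least one channel above the report length
#' (P, computed over every record, failed detections included in the
#' denominator), median/mean number of qualifying channels (M) and median/
#' mean channel length (L) over enzymes with channels (channel-free enzymes
#' excluded from M and L), enzyme counts at the 5/10/15/20 A length
#' thresholds, and pooled channel-level hydropathy/polarity means with
#' standard errors. Also reports the Spearman rank correlation between atom
#' count and qualifying channel count, and the top-10 most hydrophobic and
#' most hydrophilic channels.
#'
#' @param records List of `enzyme_record`s.
#' @param top_n Size of the extremes report.
#' @return List: `table` (data frame of cohort rows), `spearman_na_channels`,
#'   `extremes` (list `hydrophobic`, `hydrophilic`).
#' @export
summarize_cohort <- function(records, top_n = 10) {
  if (!length(records))
    chan_error("chanatomy_value_error", "no records")
  ecs <- vapply(records, function(r) r$ec_class %||% NA_character_, character(1))
  rows <- list()
  for (ec in sort(unique(ecs[!is.na(ecs)])))
    rows[[ec]] <- cohort_row(records[!is.na(ecs) & ecs == ec], ec)
  rows[["All"]] <- cohort_row(records, "All")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  nq <- vapply(records, function(r) length(qualifying(r$channels)), numeric(1))
  na <- vapply(records, `[[`, numeric(1), "n_atoms")
  ok <- !is.na(na)
  rho <- if (sum(ok) > 2 && sd(nq[ok]) > 0 && sd(na[ok]) > 0)
    cor(na[ok], nq[ok], method = "spearman") else NA_real_
  chan_tab <- do.call(rbind, lapply(records, function(r) {
    qs <- qualifying(r$channels)
    if (!length(qs)) return(NULL)
    data.frame(structure_id = r$structure_id,
               ec_class = r$ec_class %||% NA_character_,
               site_id = vapply(qs, function(ch) ch$site_id %||% NA_character_, character(1)),
               length = vapply(qs, `[[`, numeric(1), "length"),
               hydropathy = vapply(qs, function(ch) ch$physchem$hydropathy %||% NA_real_,
                                   numeric(1)),
               polarity = vapply(qs, function(ch) ch$physchem$polarity %||% NA_real_,
                                 numeric(1)),
               stringsAsFactors = FALSE)
  }))
  extremes <- list(hydrophobic = NULL, hydrophilic = NULL)
  if (!is.null(chan_tab) && nrow(chan_tab)) {
    ordh <- order(-chan_tab$hydropathy)
    extremes$hydrophobic <- head(chan_tab[ordh, ], top_n)
    extremes$hydrophilic <- head(chan_tab[order(chan_tab$hydropathy), ], top_n)
  }
  list(table = tab, spearman_na_channels = rho, channels = chan_tab,
       extremes = extremes)
}

# pooled lining residue instances of a set of records, optionally filtered
pooled_lining <- function(records, which_channels = "channels",
                          filter = NULL) {
  unlist(lapply(records, function(r) {
    chs <- qualifying(r[[which_channels]] %||% list())
    unlist(lapply(chs, function(ch) {
      lin <- ch$lining
      if (is.null(lin) || !nrow(lin)) return(character(0))
      if (!is.null(filter)) lin <- filter(lin)
      lin$resname
    }))
  }))
}

#' Frequency vectors and propensities for bottlenecks, layers and regions
#'
#' Pools lining residue instances across the cohort (each residue counted
#' once per channel it lines) and compares region compositions with the
#' pooled whole-structure composition: the channel wall as a whole, the
#' bottleneck-touching residues, the three layers, and (when generic
#' channels were computed) generic vs active-site channel walls.
#'
#' @param records List of `enzyme_record`s.
#' @return List of propensity data frames (`channel`, `bottleneck`,
#'   `internal`, `middle`, `external`, and optionally `generic` plus
#'   `generic_vs_active`), the underlying frequency vectors in
#'   `$frequencies`, and the background in `$background`.
#' @export
bottleneck_and_layer_composition <- function(records) {
  bg_counts <- Reduce(`+`, lapply(records, function(r) {
    tb <- r$residue_composition
    v <- setNames(rep(0, 20), names(.max_asa))
    v[names(tb)[names(tb) %in% names(v)]] <-
      as.numeric(tb[names(tb) %in% names(v)])
    v
  }))
  if (sum(bg_counts) == 0)
    chan_error("chanatomy_value_error", "no background residues in records")
  background <- residue_frequencies(rep(names(bg_counts), bg_counts))
  regions <- list(
    channel = pooled_lining(records),
    bottleneck = pooled_lining(records, filter = function(l)
      l[l$touches_bottleneck, , drop = FALSE]),
    internal = pooled_lining(records, filter = function(l)
      l[l$layer == "internal", , drop = FALSE]),
    middle = pooled_lining(records, filter = function(l)
      l[l$layer == "middle", , drop = FALSE]),
    external = pooled_lining(records, filter = function(l)
      l[l$layer == "external", , drop = FALSE]))
  has_generic <- any(vapply(records, function(r) !is.null(r$generic), logical(1)))
  if (has_generic)
    regions$generic <- pooled_lining(records, which_channels = "generic")
  freqs <- lapply(regions, function(x)
    if (length(x)) residue_frequencies(x) else NULL)
  tables <- lapply(freqs, function(f)
    if (!is.null(f)) propensity(f, background) else NULL)
  if (has_generic && !is.null(freqs$generic) && !is.null(freqs$channel))
    tables$generic_vs_active <- propensity(freqs$channel, freqs$generic)
  c(tables, list(frequencies = freqs, background = background))
}
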