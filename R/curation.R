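# Database curation filters and summary statistics for strength
# entries.  Complexes are rejected when the optimization did not
# converge, when the hydrogen-bond X-H distance in the optimized
# complex exceeds the role threshold (2.40 Angstrom for acceptors, 2.65
# for donors; the H...heavy-atom contact, consistent with the 1.7-2.6
# Angstrom range such contacts span), or when an imaginary normal mode
# is more negative than -50 cm^-1 (incomplete optimization).

#' Curation configuration
#' @param max_xh_hba acceptor X-H cutoff in Angstrom (default 2.40).
#' @param max_xh_hbd donor X-H cutoff in Angstrom (default 2.65).
#' @param min_freq most negative tolerated normal mode in cm^-1
#'   (default -50).
#' @export
curation_config <- function(max_xh_hba = 2.40, max_xh_hbd = 2.65,
                            min_freq = -50) {
  stopifnot(max_xh_hba > 0, max_xh_hbd > 0, min_freq <= 0)
  structure(list(max_xh_hba = max_xh_hba, max_xh_hbd = max_xh_hbd,
                 min_freq = min_freq), class = "curation_config")
}

#' Filter one complex entry
#'
#' Rules in order: converged; X-H distance within the role threshold;
#' lowest frequency not below `min_freq`.  The first failing rule is the
#' reported reason.
#'
#' @param e an `hb_entry`.
#' @param cfg a [curation_config()].
#' @return "keep", or "reject" with attribute `reason` in
#'   {not_converged, distance, frequency}.
#' @export
filter_complex_entry <- function(e, cfg = curation_config()) {
  rej <- function(reason) structure("reject", reason = reason)
  if (!is.na(e$converged) && !e$converged) return(rej("not_converged"))
  thr <- if (e$role == "HBA") cfg$max_xh_hba else cfg$max_xh_hbd
  if (!is.na(e$xh_distance) && e$xh_distance > thr)
    return(rej("distance"))
  if (!is.na(e$lowest_freq) && e$lowest_freq < cfg$min_freq)
    return(rej("frequency"))
  "keep"
}

#' Curate a list of complex entries
#' @param entries list of `hb_entry`.
#' @param cfg a [curation_config()].
#' @return list with `kept` (entries) and `rejected` (data.frame:
#'   ordinal, site_atom, reason).
#' @export
curate_entries <- function(entries, cfg = curation_config()) {
  kept <- list()
  rej <- list()
  for (e in entries) {
    v <- filter_complex_entry(e, cfg)
    if (identical(as.character(v), "keep"))
      kept[[length(kept) + 1L]] <- e
    else rej[[length(rej) + 1L]] <- data.frame(
      ordinal = e$ordinal, site_atom = e$site_atom,
      reason = attr(v, "reason"))
  }
  rejected <- if (length(rej)) do.call(rbind, rej)
  else data.frame(ordinal = integer(0), site_atom = integer(0),
                  reason = character(0))
  list(kept = kept, rejected = rejected)
}

.group_stats <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(n = 0, mean = NA, sd = NA, min = NA, max = NA))
  c(n = length(x), mean = mean(x), sd = stats::sd(x), min = min(x),
    max = max(x))
}

#' Summary statistics of a strength database
#'
#' Per group (functional class, or the whole set): n, mean, sd, min and
#' max of the calibrated free energy and of the X-H distance, plus
#' histogram bin counts at configurable widths.
#'
#' @param entries list of `hb_entry`.
#' @param group_by "functional_class" or "none".
#' @param dg_binwidth histogram bin width for dG, kJ/mol (default 1).
#' @param xh_binwidth histogram bin width for distances, Angstrom
#'   (default 0.05).
#' @return list: `table` (data.frame of group statistics, last row the
#'   total), `dg_hist`, `xh_hist` (named count vectors).
#' @export
database_summary <- function(entries, group_by = c("none",
                                                   "functional_class"),
                             dg_binwidth = 1, xh_binwidth = 0.05) {
  group_by <- match.arg(group_by)
  tab <- entries_table(entries)
  if (!nrow(tab)) stop("no entries to summarize")
  groups <- if (group_by == "functional_class") {
    g <- tab$functional_class
    g[is.na(g)] <- "(unclassified)"
    g
  } else rep("all", nrow(tab))
  rows <- list()
  for (g in sort(unique(groups))) {
    sel <- groups == g
    if (!any(sel)) { message("group ", g, " empty; omitted"); next }
    dg <- .group_stats(tab$dg_calibrated[sel])
    xh <- .group_stats(tab$xh_distance[sel])
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, n = dg[["n"]], dg_mean = dg[["mean"]],
      dg_sd = dg[["sd"]], dg_min = dg[["min"]], dg_max = dg[["max"]],
      n_xh = xh[["n"]], xh_mean = xh[["mean"]], xh_sd = xh[["sd"]],
      xh_min = xh[["min"]], xh_max = xh[["max"]])
  }
  out <- do.call(rbind, rows)
  if (group_by == "functional_class") {
    dg <- .group_stats(tab$dg_calibrated)
    xh <- .group_stats(tab$xh_distance)
    out <- rbind(out, data.frame(
      group = "(total)", n = dg[["n"]], dg_mean = dg[["mean"]],
      dg_sd = dg[["sd"]], dg_min = dg[["min"]], dg_max = dg[["max"]],
      n_xh = xh[["n"]], xh_mean = xh[["mean"]], xh_sd = xh[["sd"]],
      xh_min = xh[["min"]], xh_max = xh[["max"]]))
  }
  hist_counts <- function(x, w) {
    x <- x[!is.na(x)]
    if (!length(x)) return(stats::setNames(integer(0), character(0)))
    br <- seq(floor(min(x) / w) * w, ceiling(max(x) / w) * w + w, by = w)
    h <- graphics::hist(x, breaks = br, plot = FALSE)
    stats::setNames(h$counts, sprintf("%g", h$mids))
  }
  list(table = out,
       dg_hist = hist_counts(tab$dg_calibrated, dg_binwidth),
       xh_hist = hist_counts(tab$xh_distance, xh_binwidth))
}

#' Pearson correlation of hydrogen-bond distance and free energy
#'
#' Standard product-moment correlation over entries with both an X-H
#' distance and a calibrated free energy, optionally restricted to one
#' site element ("O", "N") -- element subsetting is unambiguous where
#' functional-class strings are not.
#'
#' @param entries list of `hb_entry`.
#' @param subset_element "all", "O" or "N".
#' @return Pearson r.
#' @export
distance_energy_correlation <- function(entries,
                                        subset_element = c("all", "O",
                                                           "N")) {
  subset_element <- match.arg(subset_element)
  tab <- entries_table(entries)
  if (subset_element != "all") tab <- tab[tab$element == subset_element, ]
  tab <- tab[!is.na(tab$xh_distance) & !is.na(tab$dg_calibrated), ]
  if (nrow(tab) < 3L)
    stop("need at least 3 entries with both distance and free energy")
  if (stats::sd(tab$xh_distance) < 1e-12 ||
      stats::sd(tab$dg_calibrated) < 1e-12)
    stop("undefined correlation: zero variance")
  stats::cor(tab$xh_distance, tab$dg_calibrated)
}

#' Compute X-H distances from complex geometries
#'
#' For entries lacking a stored distance but carrying 3D coordinates and
#' tagged atom indices for the donated hydrogen and acceptor heavy
#' atom, fills `xh_distance` from the Euclidean distance.
#'
#' @param entries list of `hb_entry` whose fragments carry coordinates
#'   and `H_IDX` / `ACCEPTOR_IDX` tags (1-based).
#' @param h_tag,acc_tag tag names holding the two indices.
#' @return the entries with `xh_distance` filled where computable.
#' @export
fill_xh_distances <- function(entries, h_tag = "H_IDX",
                              acc_tag = "ACCEPTOR_IDX") {
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (!is.na(e$xh_distance)) next
    pr <- e$fragment$props
    co <- e$fragment$coords
    if (is.null(co) || !all(c(h_tag, acc_tag) %in% names(pr))) next
    hi <- as.integer(trimws(pr[[h_tag]]))
    ai <- as.integer(trimws(pr[[acc_tag]]))
    if (anyNA(c(hi, ai)) || hi > nrow(co) || ai > nrow(co)) next
    entries[[i]]$xh_distance <- sqrt(sum((co[hi, ] - co[ai, ])^2))
  }
  entries
}
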