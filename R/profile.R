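#' Define a chain region (e.g. a CDR) by sequence-number intervals
#'
#' @param name region name.
#' @param chain chain id.
#' @param ranges list of inclusive `c(start, end)` intervals (author
#'   numbering); intervals must not overlap.
#' @return An object of class `region_def`.
#' @export
region_def <- function(name, chain, ranges) {
  if (!is.list(ranges)) ranges <- list(ranges)
  bounds <- do.call(rbind, ranges)
  if (any(bounds[, 1] > bounds[, 2])) stop("invalid interval in region ", name)
  o <- order(bounds[, 1])
  if (nrow(bounds) > 1 &&
      any(bounds[o, 1][-1] <= bounds[o, 2][-nrow(bounds)]))
    stop("overlapping intervals within region ", name)
  structure(list(name = name, chain = chain, ranges = ranges),
            class = "region_def")
}

#' Default antibody CDR region definitions
#'
#' Shipped defaults for the heavy-chain CDR2 (H 50-60), heavy-chain CDR3
#' (H 101-109) and light-chain CDR3 (L 90-96) in author numbering; override
#' chains/ranges for other numbering schemes or additional CDRs.
#'
#' @param heavy,light chain ids of the heavy and light chain.
#' @return List of [region_def()] objects.
#' @export
cdr_regions <- function(heavy = "H", light = "L") {
  list(region_def("HCDR2", heavy, list(c(50, 60))),
       region_def("HCDR3", heavy, list(c(101, 109))),
       region_def("LCDR3", light, list(c(90, 96))))
}

region_member <- function(region, chain, resno) {
  if (chain != region$chain) return(FALSE)
  any(vapply(region$ranges, function(r) resno >= r[1] && resno <= r[2], TRUE))
}

#' Per-residue interaction-energy totals for one interface side
#'
#' @param records interaction records (see [interface_energies()]), or any
#'   data.frame with `chain_i/resno_i/resid_i`, `chain_j/...` and `energy`.
#' @param side `"a"` (the i side) or `"b"` (the j side).
#' @return data.frame `key`, `chain`, `resno`, `resid`, `energy`, one row per
#'   residue, ordered by (chain, resno).
#' @export
per_residue_totals <- function(records, side = c("a", "b")) {
  side <- match.arg(side)
  sfx <- if (side == "a") "_i" else "_j"
  df <- data.frame(chain = records[[paste0("chain", sfx)]],
                   resno = records[[paste0("resno", sfx)]],
                   resid = records[[paste0("resid", sfx)]],
                   energy = records$energy, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(key = character(), chain = character(),
                      resno = integer(), resid = character(),
                      energy = numeric(), stringsAsFactors = FALSE))
  agg <- aggregate(energy ~ chain + resno + resid, data = df, FUN = sum)
  agg <- agg[order(agg$chain, agg$resno), , drop = FALSE]
  out <- data.frame(key = res_key(agg$chain, agg$resno), agg,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sum per-residue energies over named regions
#'
#' Residues outside every region are reported under `"other"`.
#'
#' @param per_residue output of [per_residue_totals()].
#' @param regions list of [region_def()] objects (must not overlap).
#' @return Named numeric vector of region totals (kcal/mol), one entry per
#'   region plus `"other"`.
#' @export
region_totals <- function(per_residue, regions) {
  nm <- vapply(regions, function(r) r$name, "")
  if (anyDuplicated(nm)) stop("duplicate region names")
  assign <- vapply(seq_len(nrow(per_residue)), function(i) {
    hits <- which(vapply(regions, region_member,
                         TRUE, chain = per_residue$chain[i],
                         resno = per_residue$resno[i]))
    if (length(hits) > 1)
      stop("regions overlap at residue ", per_residue$key[i])
    if (length(hits) == 1) nm[hits] else "other"
  }, "")
  out <- setNames(numeric(length(nm) + 1), c(nm, "other"))
  for (i in seq_len(nrow(per_residue)))
    out[assign[i]] <- out[assign[i]] + per_residue$energy[i]
  out
}

#' Regional percentage of the total interaction energy
#'
#' @param region_totals named numeric vector of region energies.
#' @param total grand total (kcal/mol); must be non-zero.
#' @return Named numeric vector of percentages (reported to 0.1).
#' @export
fraction_of_total <- function(region_totals, total) {
  if (!is.finite(total) || total == 0)
    stop("total interaction energy must be non-zero")
  round(100 * region_totals / total, 1)
}

#' Cumulative interaction-energy profile over pair distance
#'
#' `value(r)` is the sum of pair energies with `pair_distance <= r`; the
#' value at the largest cutoff equals the total over all records.
#'
#' @param records interaction records carrying `pair_distance`.
#' @param grid numeric vector of distance cutoffs (default 0 to 8 A in
#'   0.25 A steps).
#' @return data.frame `cutoff`, `energy`.
#' @export
cumulative_profile <- function(records, grid = seq(0, 8, by = 0.25)) {
  data.frame(cutoff = grid,
             energy = vapply(grid, function(r)
               sum(records$energy[records$pair_distance <= r]), 0))
}

#' Rank residues by interaction energy (most attractive first)
#'
#' @param per_residue output of [per_residue_totals()].
#' @param k number of residues to return (truncated to the available count).
#' @return `per_residue` rows sorted by ascending energy, ties broken by
#'   (chain, resno), with a `label` column like `"H_LYS65"`.
#' @export
rank_hotspots <- function(per_residue, k = nrow(per_residue)) {
  if (k < 1) stop("k must be at least 1")
  o <- order(per_residue$energy, per_residue$chain, per_residue$resno)
  out <- per_residue[o, , drop = FALSE][seq_len(min(k, nrow(per_residue))), ,
                                        drop = FALSE]
  out$label <- paste0(out$chain, "_", out$resid, out$resno)
  rownames(out) <- NULL
  out
}

#' Full hot-spot report for one interface side
#'
#' Aggregates interaction records into per-residue totals, region totals,
#' regional percentages of the grand total, and the hot-spot ranking.
#'
#' @inheritParams per_residue_totals
#' @param regions list of [region_def()] objects.
#' @param denominator `"grand"` (default; percentages of the full total
#'   including repulsive terms) or `"attractive"` (percentages of the sum of
#'   attractive per-residue totals only).
#' @return An object of class `hotspot_report`.
#' @export
hotspot_report <- function(records, regions, side = "a",
                           denominator = c("grand", "attractive")) {
  denominator <- match.arg(denominator)
  pr <- per_residue_totals(records, side)
  rt <- region_totals(pr, regions)
  total <- sum(pr$energy)
  denom <- if (denominator == "grand") total else sum(pr$energy[pr$energy < 0])
  structure(list(per_residue = pr, per_region = rt, total = total,
                 fractions = fraction_of_total(rt, denom),
                 ranking = rank_hotspots(pr), denominator = denominator),
            class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat("Hot-spot report: total", sprintf("%.2f", x$total), "kcal/mol\n")
  cat("Region totals (kcal/mol) and share of", x$denominator, "total:\n")
  for (nm in names(x$per_region))
    cat(sprintf("  %-8s %9.2f  (%5.1f%%)\n", nm, x$per_region[[nm]],
                x$fractions[[nm]]))
  cat("Top residues:\n")
  print(head(x$ranking[, c("label", "energy")], 8))
  invisible(x)
}

#' Write a hot-spot report to JSON
#'
#' @param report a `hotspot_report`.
#' @param path output path.
#' @export
write_hotspot_report <- function(report, path) {
  jsonlite::write_json(list(
    total = report$total,
    per_residue = report$per_residue,
    per_region = as.list(report$per_region),
    fractions = as.list(report$fractions),
    ranking = report$ranking), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
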