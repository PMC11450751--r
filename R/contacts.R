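#' Geometric criteria for interface contact detection
#'
#' Distance criteria (Angstrom) for hydrogen bonds (H...A and D...A upper
#' bounds, the LigPlot+/HBPLUS convention), hydrophobic carbon-carbon
#' contacts (closed interval), and salt bridges (charged-group N/O upper
#' bound).  Defaults are the values used throughout the package.
#'
#' @param hbond_ha_max H-acceptor maximum (default 2.70).
#' @param hbond_da_max donor-acceptor maximum (default 3.35).
#' @param hydrophobic_min,hydrophobic_max apolar C-C window (2.90, 3.90).
#' @param salt_bridge_max charged-group distance maximum (4.00).
#' @return An object of class `contact_criteria`.
#' @export
contact_criteria <- function(hbond_ha_max = 2.70, hbond_da_max = 3.35,
                             hydrophobic_min = 2.90, hydrophobic_max = 3.90,
                             salt_bridge_max = 4.00) {
  vals <- c(hbond_ha_max, hbond_da_max, hydrophobic_min, hydrophobic_max,
            salt_bridge_max)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("contact criteria must be positive and finite")
  if (hydrophobic_min >= hydrophobic_max)
    stop("hydrophobic_min must be smaller than hydrophobic_max")
  structure(list(hbond_ha_max = hbond_ha_max, hbond_da_max = hbond_da_max,
                 hydrophobic_min = hydrophobic_min,
                 hydrophobic_max = hydrophobic_max,
                 salt_bridge_max = salt_bridge_max),
            class = "contact_criteria")
}

empty_contacts <- function() {
  data.frame(kind = character(),
             chain1 = character(), resno1 = integer(), resid1 = character(),
             atom1 = character(),
             chain2 = character(), resno2 = integer(), resid2 = character(),
             atom2 = character(),
             d_ha = numeric(), d_da = numeric(), stringsAsFactors = FALSE)
}

contact_row <- function(kind, a1, a2, d_ha, d_da) {
  data.frame(kind = kind,
             chain1 = a1$chain, resno1 = a1$resno, resid1 = a1$resid,
             atom1 = a1$elety,
             chain2 = a2$chain, resno2 = a2$resno, resid2 = a2$resid,
             atom2 = a2$elety,
             d_ha = d_ha, d_da = d_da, stringsAsFactors = FALSE)
}

split_groups <- function(structure, chains1, chains2) {
  if (length(intersect(chains1, chains2)) > 0)
    stop("chain groups overlap: ", paste(intersect(chains1, chains2), collapse = ","))
  a <- structure$atoms
  list(a1 = a[a$chain %in% chains1 & !is_water_resid(a$resid), , drop = FALSE],
       a2 = a[a$chain %in% chains2 & !is_water_resid(a$resid), , drop = FALSE])
}

#' Detect interface hydrogen bonds
#'
#' Scans donor/acceptor atom pairs across the two chain groups using a fixed
#' chemistry table (N/O/S donors bearing hydrogens; N/O acceptors).  In
#' `heavy_only` mode a bond is recorded when the donor-acceptor distance is
#' at most `hbond_da_max`; in `with_hydrogens` mode the hydrogen-acceptor
#' distance must additionally be at most `hbond_ha_max` (hydrogens are
#' located as H atoms within 1.25 A of the donor, in the donor's residue).
#'
#' @param structure a `Structure`.
#' @param chains1,chains2 chain ids of the two interface sides.
#' @param criteria a [contact_criteria()] object.
#' @param mode `"heavy_only"` or `"with_hydrogens"`.
#' @return data.frame of contact records (one row per qualifying donor
#'   to acceptor atom pair, donor side first).
#' @export
detect_hbonds <- function(structure, chains1, chains2,
                          criteria = contact_criteria(),
                          mode = c("heavy_only", "with_hydrogens")) {
  mode <- match.arg(mode)
  gr <- split_groups(structure, chains1, chains2)
  if (mode == "with_hydrogens" && !any(structure$atoms$elesy == "H"))
    stop("with_hydrogens mode requires hydrogens in the structure")
  out <- rbind(scan_hbonds(gr$a1, gr$a2, criteria, mode),
               scan_hbonds(gr$a2, gr$a1, criteria, mode))
  if (nrow(out)) out[order(out$chain1, out$resno1, out$chain2, out$resno2), ,
                     drop = FALSE]
  else out
}

scan_hbonds <- function(ad, aa, criteria, mode) {
  out <- empty_contacts()
  don <- ad[mapply(function(r, e) e %in% hb_donor_atoms(r), ad$resid, ad$elety), ,
            drop = FALSE]
  acc <- aa[mapply(function(r, e) e %in% hb_acceptor_atoms(r), aa$resid, aa$elety), ,
            drop = FALSE]
  if (nrow(don) == 0L || nrow(acc) == 0L) return(out)
  dd <- cross_dist(coords(don), coords(acc))
  hyd <- ad[ad$elesy == "H", , drop = FALSE]
  for (i in seq_len(nrow(don))) for (j in seq_len(ncol(dd))) {
    if (dd[i, j] > criteria$hbond_da_max) next
    d_ha <- NA_real_
    if (mode == "with_hydrogens") {
      hres <- hyd[hyd$chain == don$chain[i] & hyd$resno == don$resno[i] &
                  hyd$insert == don$insert[i], , drop = FALSE]
      if (nrow(hres) == 0L) next
      dh <- cross_dist(coords(hres), coords(don[i, , drop = FALSE]))[, 1]
      hon <- hres[dh <= 1.25, , drop = FALSE]
      if (nrow(hon) == 0L) next
      dha <- cross_dist(coords(hon), coords(acc[j, , drop = FALSE]))[, 1]
      d_ha <- min(dha)
      if (d_ha > criteria$hbond_ha_max) next
    }
    out <- rbind(out, contact_row("hbond", don[i, ], acc[j, ], d_ha, dd[i, j]))
  }
  out
}

#' Detect interface hydrophobic contacts
#'
#' One record per residue pair with at least one apolar-carbon/apolar-carbon
#' distance inside `[hydrophobic_min, hydrophobic_max]`; apolar carbons are
#' carbons not bonded to N or O (fixed per-residue table).  The reported atom
#' pair is the closest qualifying one.
#'
#' @inheritParams detect_hbonds
#' @return data.frame of contact records.
#' @export
detect_hydrophobic <- function(structure, chains1, chains2,
                               criteria = contact_criteria()) {
  gr <- split_groups(structure, chains1, chains2)
  pick <- function(a) a[mapply(function(r, e)
    e %in% APOLAR_CARBONS[[toupper(r)]], a$resid, a$elety), , drop = FALSE]
  c1 <- pick(gr$a1); c2 <- pick(gr$a2)
  out <- empty_contacts()
  if (nrow(c1) == 0L || nrow(c2) == 0L) return(out)
  dd <- cross_dist(coords(c1), coords(c2))
  ok <- dd >= criteria$hydrophobic_min & dd <= criteria$hydrophobic_max
  k1 <- atom_res_keys(c1); k2 <- atom_res_keys(c2)
  for (key1 in unique(k1)) for (key2 in unique(k2)) {
    sub <- dd[k1 == key1, k2 == key2, drop = FALSE]
    oksub <- ok[k1 == key1, k2 == key2, drop = FALSE]
    if (!any(oksub)) next
    sub[!oksub] <- Inf
    idx <- arrayInd(which.min(sub), dim(sub))
    a1 <- c1[which(k1 == key1)[idx[1]], ]
    a2 <- c2[which(k2 == key2)[idx[2]], ]
    out <- rbind(out, contact_row("hydrophobic", a1, a2, NA_real_, min(sub)))
  }
  out
}

#' Detect interface salt bridges
#'
#' One record per Asp/Glu carboxylate-oxygen to Lys/Arg/His basic-nitrogen
#' residue pair with minimum distance at most `salt_bridge_max`.
#'
#' @inheritParams detect_hbonds
#' @return data.frame of contact records (acidic side listed first).
#' @export
detect_salt_bridges <- function(structure, chains1, chains2,
                                criteria = contact_criteria()) {
  gr <- split_groups(structure, chains1, chains2)
  pick <- function(a, tab) a[mapply(function(r, e) {
    g <- tab[[toupper(r)]]; !is.null(g) && e %in% g
  }, a$resid, a$elety), , drop = FALSE]
  out <- empty_contacts()
  for (ori in 1:2) {
    ac <- pick(if (ori == 1) gr$a1 else gr$a2, SB_ACIDIC)
    ba <- pick(if (ori == 1) gr$a2 else gr$a1, SB_BASIC)
    if (nrow(ac) == 0L || nrow(ba) == 0L) next
    dd <- cross_dist(coords(ac), coords(ba))
    ka <- atom_res_keys(ac); kb <- atom_res_keys(ba)
    for (key1 in unique(ka)) for (key2 in unique(kb)) {
      sub <- dd[ka == key1, kb == key2, drop = FALSE]
      if (min(sub) > criteria$salt_bridge_max) next
      idx <- arrayInd(which.min(sub), dim(sub))
      a1 <- ac[which(ka == key1)[idx[1]], ]
      a2 <- ba[which(kb == key2)[idx[2]], ]
      out <- rbind(out, contact_row("salt_bridge", a1, a2, NA_real_, min(sub)))
    }
  }
  out
}

#' Summarize contact conservation across conformations
#'
#' Counts, for every contact key (residue pair plus contact kind), how many
#' of the supplied per-conformation contact lists contain it.
#'
#' @param contact_lists list of contact record data.frames, one per
#'   conformation.
#' @return An object of class `conservation_summary`: a list with `counts`
#'   (data.frame `key`, `kind`, `res1`, `res2`, `count`) and
#'   `n_conformations`.
#' @export
conservation <- function(contact_lists) {
  if (length(contact_lists) == 0L) stop("need at least one conformation")
  keys <- lapply(contact_lists, function(df) {
    if (nrow(df) == 0L) return(character())
    unique(paste(df$kind, res_key(df$chain1, df$resno1),
                 res_key(df$chain2, df$resno2), sep = "|"))
  })
  all_keys <- unique(unlist(keys))
  counts <- vapply(all_keys, function(k)
    sum(vapply(keys, function(x) k %in% x, TRUE)), 0L)
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  out <- data.frame(key = all_keys,
                    kind = vapply(parts, `[`, "", 1),
                    res1 = vapply(parts, `[`, "", 2),
                    res2 = vapply(parts, `[`, "", 3),
                    count = unname(counts), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$key), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(counts = out, n_conformations = length(contact_lists)),
            class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat("Contact conservation over", x$n_conformations, "conformation(s):",
      nrow(x$counts), "distinct contact(s)\n")
  if (nrow(x$counts)) print(head(x$counts, 10))
  invisible(x)
}

#' Write contact records to CSV
#'
#' @param contacts contact record data.frame.
#' @param path output CSV path.
#' @export
write_contacts <- function(contacts, path) {
  write.csv(contacts, path, row.names = FALSE)
  invisible(path)
}
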