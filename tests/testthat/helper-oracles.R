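# Independent oracles, deliberately implemented with different algorithms
# than the package code they check.

# Exhaustive isotopologue oracle for small formulas (<= ~10 atoms): every
# atom's isotope choice is enumerated explicitly, abundances multiplied,
# and isotopologues aggregated into unit nominal-mass bins.
oracle_pattern_exhaustive <- function(counts, n_labels = 4L,
                                      constants = npsid_constants()) {
  atoms <- rep(names(counts), counts)
  iso <- lapply(atoms, function(el) constants$isotopes[[el]])
  grid <- expand.grid(lapply(iso, function(d) seq_len(nrow(d))),
                      KEEP.OUT.ATTRS = FALSE)
  mass <- rep(0, nrow(grid)); ab <- rep(1, nrow(grid))
  for (j in seq_along(iso)) {
    mass <- mass + iso[[j]]$mass[grid[[j]]]
    ab <- ab * iso[[j]]$abundance[grid[[j]]]
  }
  mono <- sum(vapply(iso, function(d) d$mass[1L], 0))
  shift <- round(mass - mono)
  out <- numeric(n_labels)
  for (s in 0:(n_labels - 1L)) out[s + 1L] <- sum(ab[shift == s])
  out / out[1L]
}

# Sequential-convolution oracle for larger formulas: atom-by-atom
# convolution of (nominal shift, abundance) distributions truncated at the
# requested number of labels.
oracle_pattern_convolve <- function(counts, n_labels = 4L,
                                    constants = npsid_constants()) {
  smax <- n_labels - 1L
  dist <- c(1, rep(0, smax))  # abundance per shift 0..smax, relative scale
  for (el in names(counts)) {
    d <- constants$isotopes[[el]]
    shifts <- round(d$mass - d$mass[1L])
    atom <- numeric(smax + 1L)
    for (i in seq_len(nrow(d))) {
      if (shifts[i] <= smax) atom[shifts[i] + 1L] <-
          atom[shifts[i] + 1L] + d$abundance[i]
    }
    for (k in seq_len(counts[[el]])) {
      new <- numeric(smax + 1L)
      for (a in 0:smax) for (b in 0:(smax - a)) {
        new[a + b + 1L] <- new[a + b + 1L] + dist[a + 1L] * atom[b + 1L]
      }
      dist <- new
    }
  }
  dist / dist[1L]
}

# Brute-force composition search: plain nested loops, no vectorisation,
# no shared code with search_compositions().
oracle_search <- function(observed_mz, ranges, ppm_tol, rdbe_range = c(0, 25),
                          constants = npsid_constants()) {
  mono <- vapply(names(constants$isotopes),
                 function(el) constants$isotopes[[el]]$mass[1L], 0)
  hits <- character(0)
  for (nc in ranges$C[1]:ranges$C[2])
    for (nh in ranges$H[1]:ranges$H[2])
      for (nn in ranges$N[1]:ranges$N[2])
        for (no in ranges$O[1]:ranges$O[2]) {
          if (nc + nh + nn + no == 0) next
          mz <- nc * mono["C"] + nh * mono["H"] + nn * mono["N"] +
            no * mono["O"] + mono["H"] - constants$electron_mass
          if (abs((observed_mz - mz) / mz * 1e6) > ppm_tol) next
          rd <- nc - nh / 2 + nn / 2 + 1
          if (rd < rdbe_range[1] || rd > rdbe_range[2]) next
          hits <- c(hits, paste0("C", nc, "H", nh, "N", nn, "O", no))
        }
  hits
}

# canonicalise an oracle hit key to Hill-order formula text
oracle_key_to_formula <- function(key) {
  n <- as.integer(strsplit(gsub("[CHNO]", " ", key), " +")[[1]][-1])
  format(parse_formula(paste0(
    if (n[1]) paste0("C", n[1]) else "", if (n[2]) paste0("H", n[2]) else "",
    if (n[3]) paste0("N", n[3]) else "", if (n[4]) paste0("O", n[4]) else "")))
}

ref_table <- function() meo_pcp_reference()
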