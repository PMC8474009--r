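# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration / naive computation and never call the
# implementation paths they check (beyond the shared constants table, which
# the package fixes as the single source of masses).

# all tryptic peptides of a protein by exhaustive enumeration over cleavage
# boundaries (cut after every K/R), keeping runs with <= max_missed internal
# cleavage sites
oracle_digest <- function(sequence, max_missed) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < n]
  bounds <- c(0L, sites, n)
  out <- list()
  for (a in seq_len(length(bounds) - 1L)) {
    for (b in (a + 1L):length(bounds)) {
      missed <- b - a - 1L
      if (missed > max_missed) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(sequence, bounds[a] + 1L, bounds[b]),
        start = bounds[a] + 1L, end = bounds[b],
        missed_cleavages = missed, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$missed_cleavages), , drop = FALSE]
}

# independent residue-mass summation over the package's constants table
oracle_peptide_mass <- function(sequence, phospho = integer(),
                                heavy_pos = NULL) {
  cst <- mrmassay::mass_constants()
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  total <- cst$water
  for (i in seq_along(chars)) {
    total <- total + cst$residues[[chars[i]]]
    if (i %in% phospho) total <- total + cst$mods[["phospho"]]
    if (!is.null(heavy_pos) && i == heavy_pos) {
      total <- total + cst$mods[[paste0("heavy_", chars[i])]]
    }
  }
  total
}

oracle_fragment_mz <- function(sequence, phospho, series, index, charge) {
  cst <- mrmassay::mass_constants()
  n <- nchar(sequence)
  span <- if (series == "b") 1:index else (n - index + 1L):n
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  neutral <- sum(vapply(span, function(i) {
    m <- cst$residues[[chars[i]]]
    if (i %in% phospho) m <- m + cst$mods[["phospho"]]
    m
  }, numeric(1)))
  if (series == "y") neutral <- neutral + cst$water
  (neutral + charge * cst$proton) / charge
}

# naive O(n^2) Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (k in seq_len(n)) {
    i <- o[k]
    adj[i] <- min(1, min(p[o[k:n]] * n / seq.int(k, n)))
  }
  adj
}

# random peptide sequence ending in K/R (tryptic-looking)
random_peptide <- function(len) {
  aa <- setdiff(names(mrmassay::mass_constants()$residues), c("K", "R"))
  paste0(paste(sample(aa, len - 1L, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

# spectral-library entry fixture with explicit intensities
toy_library_entry <- function(sequence = "ADSVEGTLK", phospho = 3L,
                              intensities = NULL, charge = 2L) {
  pep <- mrmassay::modified_peptide(sequence, phospho = phospho,
                                    charge = charge)
  n <- nchar(sequence)
  frags <- expand.grid(series = c("b", "y"), index = seq_len(n - 1L),
                       charge = 1L, stringsAsFactors = FALSE)
  if (is.null(intensities)) {
    intensities <- rev(seq_len(nrow(frags))) / nrow(frags)
  }
  frags$intensity <- intensities
  list(peptide = pep, fragments = frags, retention_time = 30)
}
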