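#' Look up observation evidence for a modified peptide form
#'
#' @param evidence data.frame with columns `modified_sequence`, `count`,
#'   `routes` (comma-separated subset of `IMAC`, `pY`; may be empty).
#' @param sequence unmodified peptide sequence.
#' @param phospho integer positions of phosphorylation within the peptide.
#' @return list with `count` (0 when the form was never observed) and
#'   `routes` (character vector, possibly empty).
#' @export
evidence_lookup <- function(evidence, sequence, phospho) {
  key <- modified_sequence(sequence, phospho)
  if (is.null(evidence) || nrow(evidence) == 0L) {
    return(list(count = 0L, routes = character(0)))
  }
  hit <- which(evidence$modified_sequence == key)
  if (length(hit) == 0L) {
    return(list(count = 0L, routes = character(0)))
  }
  routes <- evidence$routes[hit[1L]]
  routes <- if (is.na(routes) || !nzchar(routes)) character(0) else
    strsplit(routes, ",", fixed = TRUE)[[1L]]
  list(count = as.integer(sum(evidence$count[hit])), routes = trimws(routes))
}

#' Select one peptide form for a phosphosite
#'
#' Applies the panel selection rules, in order: (1) forms longer than 40
#' residues are dropped (all too long: reject `too_long`); (2) forms shorter
#' than 6 residues are dropped -- a short fully cleaved form is only carried by
#' a 6--40-residue missed-cleaved "rescue" form, so when no 6--40 form exists
#' the site is rejected `too_short_no_rescue`; (3) among survivors the form
#' with the highest observation count wins, ties broken by fewest missed
#' cleavages, then shortest length; (4) a winner with zero observations is
#' rejected `not_observed` for nominated sites unless `include_unobserved`;
#' (5) a singly phosphorylated form is preferred over a doubly phosphorylated
#' one unless the doubly form is at least `prevalence_factor` times more
#' frequently observed.
#'
#' @param candidates data.frame of candidate forms with columns `sequence`,
#'   `missed_cleavages`, `length` and list-column `phospho` (integer positions
#'   within the peptide; 1 or 2 sites per form).
#' @param evidence observation-evidence table (see [evidence_lookup()]).
#' @param source `"nominated"` or `"discovery"`; discovery-derived sites are
#'   by construction observed and skip rule (4).
#' @param include_unobserved keep a never-observed nominated form anyway
#'   (models panel entries retained for biological importance).
#' @param prevalence_factor fold-excess at which a doubly phosphorylated form
#'   displaces the singly phosphorylated one.
#' @return one-row data.frame: `status` (`selected`/`rejected`),
#'   `rejection_reason` (`none`, `too_long`, `too_short_no_rescue`,
#'   `not_observed`), and for selected entries the winning form's `sequence`,
#'   `phospho` (list-column), `modified_sequence`, `missed_cleavages`,
#'   `length`, `observation_count`.
#' @export
select_peptide <- function(candidates, evidence = NULL, source = "nominated",
                           include_unobserved = FALSE, prevalence_factor = 3) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop("empty candidate list", call. = FALSE)
  }
  source <- match.arg(source, c("nominated", "discovery"))
  if (!"phospho" %in% names(candidates)) {
    candidates$phospho <- as.list(candidates$phospho_offset)
  }
  reject <- function(reason) {
    data.frame(status = "rejected", rejection_reason = reason,
               sequence = NA_character_, modified_sequence = NA_character_,
               missed_cleavages = NA_integer_, length = NA_integer_,
               observation_count = NA_integer_, stringsAsFactors = FALSE)
  }
  ok_len <- candidates$length <= 40L
  if (!any(ok_len)) return(reject("too_long"))
  in_range <- ok_len & candidates$length >= 6L
  if (!any(in_range)) return(reject("too_short_no_rescue"))
  surv <- candidates[in_range, , drop = FALSE]
  surv$observation_count <- vapply(seq_len(nrow(surv)), function(i) {
    evidence_lookup(evidence, surv$sequence[i], surv$phospho[[i]])$count
  }, integer(1))
  n_phospho <- lengths(surv$phospho)

  best_of <- function(rows) {
    o <- order(-rows$observation_count, rows$missed_cleavages, rows$length)
    rows[o[1L], , drop = FALSE]
  }
  singly <- surv[n_phospho == 1L, , drop = FALSE]
  doubly <- surv[n_phospho == 2L, , drop = FALSE]
  win <- if (nrow(singly) == 0L) {
    best_of(doubly)
  } else if (nrow(doubly) == 0L) {
    best_of(singly)
  } else {
    bs <- best_of(singly); bd <- best_of(doubly)
    if (bd$observation_count >= prevalence_factor * bs$observation_count &&
        bd$observation_count > 0L) bd else bs
  }
  if (win$observation_count == 0L && source == "nominated" &&
      !include_unobserved) {
    return(reject("not_observed"))
  }
  data.frame(
    status = "selected", rejection_reason = "none",
    sequence = win$sequence,
    modified_sequence = modified_sequence(win$sequence, win$phospho[[1L]]),
    missed_cleavages = win$missed_cleavages, length = win$length,
    observation_count = win$observation_count,
    phospho = I(win$phospho), stringsAsFactors = FALSE
  )
}

#' Genes sharing a peptide sequence
#'
#' Exact-substring search of the unmodified peptide against every protein in
#' the proteome (no I/L folding). Shared peptides report all source genes,
#' e.g. a peptide carrying the common T35 tryptic window of the two MOB1
#' paralogs returns both gene symbols.
#'
#' @param peptide unmodified peptide sequence.
#' @param proteome data.frame with columns `gene_symbol`, `sequence`.
#' @return character vector of gene symbols (>= 1 for a peptide taken from
#'   the proteome).
#' @export
annotate_uniqueness <- function(peptide, proteome) {
  stopifnot(nrow(proteome) > 0L)
  hits <- vapply(proteome$sequence, function(s)
    grepl(peptide, s, fixed = TRUE), logical(1))
  unique(proteome$gene_symbol[hits])
}

#' Conservation of a peptide in a second proteome
#'
#' `TRUE` iff the unmodified peptide occurs verbatim in any sequence of the
#' other species' proteome -- the criterion under which an assay peptide is
#' directly transferable across species.
#'
#' @param peptide unmodified peptide sequence.
#' @param other_proteome data.frame with a `sequence` column.
#' @return logical flag.
#' @export
check_conservation <- function(peptide, other_proteome) {
  stopifnot(nrow(other_proteome) > 0L)
  any(vapply(other_proteome$sequence, function(s)
    grepl(peptide, s, fixed = TRUE), logical(1)))
}

#' Assign the enrichment route of a selected panel entry
#'
#' pS/pT-only peptides are enriched by IMAC. pY-containing peptides go to the
#' pY-antibody route, unless prior evidence shows detection under both IMAC
#' and pY enrichment, in which case the peptide is routed to the combined
#' IMACpY pool (spiked with either method).
#'
#' @param modified_seq modified peptide string (phospho annotations).
#' @param evidence_routes character vector of routes under which the form was
#'   previously detected (subset of `IMAC`, `pY`).
#' @return one of `"IMAC"`, `"pY"`, `"IMACpY"`.
#' @export
assign_route <- function(modified_seq, evidence_routes = character(0)) {
  has_py <- grepl("(pY)", modified_seq, fixed = TRUE)
  if (!has_py) return("IMAC")
  if (all(c("IMAC", "pY") %in% evidence_routes)) "IMACpY" else "pY"
}

#' Place the stable-isotope label on a peptide
#'
#' Tryptic peptides end in K or R, which take the 13C/15N label. Peptides at
#' a protein C-terminus lack that residue; those fall back to an N-terminal
#' K/R, then to an internal leucine or proline.
#'
#' @param sequence peptide sequence.
#' @param is_protein_cterm whether the peptide ends at the protein C-terminus.
#' @return list with `position` (1-based) and `residue`.
#' @export
choose_heavy_label <- function(sequence, is_protein_cterm = FALSE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (!is_protein_cterm || chars[n] %in% c("K", "R")) {
    if (!chars[n] %in% c("K", "R")) {
      stop("non-C-terminal peptide must end in K or R", call. = FALSE)
    }
    return(list(position = n, residue = chars[n]))
  }
  if (chars[1L] %in% c("K", "R")) {
    return(list(position = 1L, residue = chars[1L]))
  }
  lp <- which(chars %in% c("L", "P"))
  if (length(lp) == 0L) {
    stop("no labelable residue (K/R/L/P) in peptide ", sequence,
         call. = FALSE)
  }
  list(position = lp[1L], residue = chars[lp[1L]])
}

#' Build a phosphopeptide panel from a proteome and site nominations
#'
#' Runs the full selection pipeline per nominated site: digestion of the
#' parent protein, mapping the site onto candidate tryptic forms (optionally
#' expanding doubly phosphorylated forms recorded in the evidence table),
#' form selection, uniqueness annotation, enrichment routing and heavy-label
#' placement. Rejected sites are retained with their rejection reason.
#'
#' @param proteome data.frame from [read_proteome_fasta()] with columns
#'   `accession`, `gene_symbol`, `sequence`.
#' @param sites data.frame with columns `gene_symbol`, `residue`, `position`,
#'   `source` (`nominated`/`discovery`).
#' @param evidence observation-evidence table (`modified_sequence`, `count`,
#'   `routes`), or `NULL`.
#' @param max_missed maximum missed cleavages considered (default 2).
#' @param prevalence_factor doubly-vs-singly phosphorylation preference factor.
#' @param include_unobserved either `FALSE`, `TRUE`, or a character vector of
#'   site labels (`"GENE pS123"`) exempted from the observation requirement.
#' @param proline_rule forwarded to [digest()].
#' @return data.frame with one row per site: `gene`, `site_label`, `status`,
#'   `rejection_reason`, and for selected entries `sequence`,
#'   `modified_sequence`, `phospho_offsets` (comma-joined), `length`,
#'   `missed_cleavages`, `observation_count`, `enrichment_route`,
#'   `heavy_label_position`, `heavy_label_residue`, `shared_genes`
#'   (`/`-joined).
#' @export
design_panel <- function(proteome, sites, evidence = NULL, max_missed = 2L,
                         prevalence_factor = 3, include_unobserved = FALSE,
                         proline_rule = FALSE) {
  stopifnot(nrow(proteome) > 0L, nrow(sites) > 0L)
  digests <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    gene <- sites$gene_symbol[i]
    label <- sprintf("%s p%s%d", gene, sites$residue[i], sites$position[i])
    pidx <- match(gene, proteome$gene_symbol)
    if (is.na(pidx)) {
      stop("gene ", gene, " not in proteome", call. = FALSE)
    }
    prot <- proteome$sequence[pidx]
    if (!exists(gene, envir = digests)) {
      assign(gene, digest(prot, max_missed = max_missed,
                          proline_rule = proline_rule), envir = digests)
    }
    cands <- map_site(sites$position[i], sites$residue[i],
                      get(gene, envir = digests), protein_sequence = prot)
    if (nrow(cands) == 0L) {
      stop("site ", label, " not covered by any tryptic peptide",
           call. = FALSE)
    }
    cands$phospho <- as.list(cands$phospho_offset)
    cands <- .expand_multiply_phospho(cands, evidence)
    inc <- if (is.logical(include_unobserved)) include_unobserved else
      label %in% include_unobserved
    sel <- select_peptide(cands, evidence, source = sites$source[i],
                          include_unobserved = inc,
                          prevalence_factor = prevalence_factor)
    row <- data.frame(
      gene = gene, site_label = label, status = sel$status,
      rejection_reason = sel$rejection_reason,
      sequence = sel$sequence, modified_sequence = sel$modified_sequence,
      phospho_offsets = NA_character_, length = sel$length,
      missed_cleavages = sel$missed_cleavages,
      observation_count = sel$observation_count,
      enrichment_route = NA_character_,
      heavy_label_position = NA_integer_,
      heavy_label_residue = NA_character_,
      shared_genes = NA_character_, stringsAsFactors = FALSE
    )
    if (sel$status == "selected") {
      row$phospho_offsets <- paste(sel$phospho[[1L]], collapse = ",")
      ev <- evidence_lookup(evidence, sel$sequence, sel$phospho[[1L]])
      row$enrichment_route <- assign_route(sel$modified_sequence, ev$routes)
      cterm <- grepl(paste0(sel$sequence, "$"), prot)
      is_cterm <- cterm && !substr(sel$sequence, sel$length, sel$length) %in%
        c("K", "R")
      hl <- choose_heavy_label(sel$sequence, is_protein_cterm = is_cterm)
      row$heavy_label_position <- hl$position
      row$heavy_label_residue <- hl$residue
      row$shared_genes <- paste(sort(annotate_uniqueness(sel$sequence,
                                                         proteome)),
                                collapse = "/")
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# add doubly phosphorylated variants of each candidate that appear in the
# evidence table (second site anywhere on another S/T/Y of the same peptide)
.expand_multiply_phospho <- function(cands, evidence) {
  if (is.null(evidence) || nrow(evidence) == 0L) return(cands)
  extra <- list()
  for (i in seq_len(nrow(cands))) {
    seqc <- strsplit(cands$sequence[i], "", fixed = TRUE)[[1L]]
    p0 <- cands$phospho[[i]]
    others <- setdiff(which(seqc %in% c("S", "T", "Y")), p0)
    for (p2 in others) {
      ph <- sort(c(p0, p2))
      if (evidence_lookup(evidence, cands$sequence[i], ph)$count > 0L) {
        row <- cands[i, , drop = FALSE]
        row$phospho <- list(ph)
        extra[[length(extra) + 1L]] <- row
      }
    }
  }
  if (length(extra) == 0L) return(cands)
  rbind(cands, do.call(rbind, extra))
}

#' Panel configuration QC summary
#'
#' Bookkeeping over the assay-development funnel: peptides synthesized, lost
#' at instrument configuration, lost at the enrichment step, and the surviving
#' working panel with its detection success rate (reported to whole percent).
#'
#' @param n_synthesized number of synthesized SIL peptides.
#' @param n_config_fail peptides failing LC/MS assay configuration.
#' @param n_enrich_fail peptides failing the pY-antibody or IMAC enrichment.
#' @return list with `n_surviving`, `success_rate_pct` (rounded to the whole
#'   percent), `success_rate_raw`.
#' @examples
#' panel_qc_summary(352, 24, 30)  # 298 peptides, 85%
#' @export
panel_qc_summary <- function(n_synthesized, n_config_fail, n_enrich_fail) {
  stopifnot(n_synthesized > 0, n_config_fail >= 0, n_enrich_fail >= 0)
  n_surv <- n_synthesized - n_config_fail - n_enrich_fail
  if (n_surv < 0) stop("failures exceed synthesized count", call. = FALSE)
  raw <- 100 * n_surv / n_synthesized
  list(n_surviving = n_surv, success_rate_pct = round(raw),
       success_rate_raw = raw)
}

#' Quantification rate among detected peptides
#'
#' @param n_quantified peptides quantified at the condition of interest.
#' @param n_detected peptides detected in the experiment overall.
#' @return list with `rate_pct` (whole percent) and `rate_raw`.
#' @examples
#' quantification_rate(74, 96)  # 77%
#' @export
quantification_rate <- function(n_quantified, n_detected) {
  stopifnot(n_detected > 0, n_quantified >= 0, n_quantified <= n_detected)
  raw <- 100 * n_quantified / n_detected
  list(rate_pct = round(raw), rate_raw = raw)
}

#' Assay-unique sites from a detection overlap
#'
#' Sites detected by the targeted assay but absent from a reference discovery
#' dataset, given the overlap split into fully covered and partially covered
#' subsets.
#'
#' @param n_detected sites detected by the targeted assay.
#' @param n_overlap_full overlap sites seen in all discovery samples.
#' @param n_overlap_partial overlap sites seen in a subset of discovery
#'   samples.
#' @return number of assay-unique sites.
#' @examples
#' assay_unique_sites(140, 58, 28)  # 54
#' @export
assay_unique_sites <- function(n_detected, n_overlap_full, n_overlap_partial) {
  u <- n_detected - (n_overlap_full + n_overlap_partial)
  if (u < 0) stop("overlap exceeds detected count", call. = FALSE)
  u
}
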