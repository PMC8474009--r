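#' Default run configuration
#'
#' The numeric operating constants of the workflow: route-specific light
#' detection thresholds (250 counts for pY-antibody samples, 300 for IMAC),
#' a 10-min retention-time scheduling window, mixture size bounds per route,
#' collision-energy coefficients per charge, the interference cutoff, the
#' integration half-window in FWHM units, significance levels and the seed.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    py_height_threshold = 250,
    imac_height_threshold = 300,
    rt_window = 10,
    mixture_bounds = list(IMAC = c(43L, 50L), pY = c(31L, 40L)),
    ce_coefficients = list(
      `2` = list(slope = 0.0339, intercept = 2.3597),
      `3` = list(slope = 0.0295, intercept = 2.4141)
    ),
    interference_cutoff = 0.2,
    boundary_fwhm_k = 1.5,
    alpha_cell_line = 0.05,
    alpha_tissue = 0.1,
    imputation_shift = 1,
    seed = 1L
  )
}

#' Read a run configuration file
#'
#' YAML-formatted structured text; absent keys fall back to
#' [default_config()], unknown keys are rejected by name. Nested keys
#' (`mixture_bounds`, `ce_coefficients`) replace the default wholesale when
#' present.
#'
#' @param path file path; an empty or absent-key file yields all defaults.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- default_config()
  user <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed config file ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (is.null(user)) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key '", unknown[[1L]], "'", call. = FALSE)
  }
  for (key in names(user)) cfg[[key]] <- user[[key]]
  for (key in c("py_height_threshold", "imac_height_threshold",
                "rt_window")) {
    if (cfg[[key]] <= 0) stop("config key ", key, " must be > 0",
                              call. = FALSE)
  }
  cfg
}

#' Read a proteome FASTA
#'
#' Headers are parsed as `accession|gene`; sequences are validated against
#' the 20 standard residues.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `accession`, `gene_symbol`, `sequence`.
#' @export
read_proteome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    stop("FASTA header not of the form 'accession|gene': ",
         headers[bad][[1L]], call. = FALSE)
  }
  seqs <- as.character(aa)
  for (s in seqs) check_sequence(s, "protein sequence")
  data.frame(
    accession = vapply(parts, `[[`, character(1), 1L),
    gene_symbol = vapply(parts, `[[`, character(1), 2L),
    sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a proteome FASTA with `accession|gene` headers
#'
#' @param proteome data.frame with `accession`, `gene_symbol`, `sequence`.
#' @param path output path.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- paste(proteome$accession, proteome$gene_symbol, sep = "|")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

.read_tsv <- function(path, required) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phosphosite nominations TSV (gene, residue, position, source)
#' @param path TSV path.
#' @return data.frame with `gene_symbol`, `residue`, `position`, `source`.
#' @export
read_sites <- function(path) {
  df <- .read_tsv(path, c("gene_symbol", "residue", "position", "source"))
  df$position <- as.integer(df$position)
  df
}

#' Read an observation-evidence TSV (modified_sequence, count, routes)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_evidence <- function(path) {
  df <- .read_tsv(path, c("modified_sequence", "count", "routes"))
  df$count <- as.integer(df$count)
  df$routes <- as.character(df$routes)
  df
}

#' Write / read a panel table
#'
#' One row per site (selected or rejected), shared genes `/`-joined.
#'
#' @param panel data.frame from [design_panel()].
#' @param path TSV path.
#' @export
write_panel <- function(panel, path) .write_tsv(panel, path)

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  .read_tsv(path, c("gene", "site_label", "status", "rejection_reason",
                    "sequence", "modified_sequence"))
}

#' Read a long-format chromatogram TSV
#'
#' Columns: `sample`, `peptide`, `transition` (fragment ion, e.g. `y5`),
#' `label` (`light`/`heavy`), `time` (min), `intensity` (counts).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_chromatograms <- function(path) {
  df <- .read_tsv(path, c("sample", "peptide", "transition", "label",
                          "time", "intensity"))
  df$time <- as.numeric(df$time)
  df$intensity <- as.numeric(df$intensity)
  df
}

#' Write / read a quantification table
#' @param records data.frame from [quantify_chromatograms()].
#' @param path TSV path.
#' @export
write_quant <- function(records, path) .write_tsv(records, path)

#' @rdname write_quant
#' @export
read_quant <- function(path) {
  df <- .read_tsv(path, c("sample", "peptide", "par", "category"))
  df$par <- as.numeric(df$par)
  df$category <- as.integer(df$category)
  df
}

#' Write a transition list CSV
#'
#' Fixed column order with 5-decimal m/z formatting, one row per transition.
#'
#' @param method_table data.frame (the `table` element of [build_method()]
#'   plus `protein` and `modified_sequence`, `isotope_label` columns).
#' @param path CSV path.
#' @export
write_transitions <- function(method_table, path) {
  tab <- method_table
  for (col in c("precursor_mz", "product_mz")) {
    if (col %in% names(tab)) tab[[col]] <- sprintf("%.5f", tab[[col]])
  }
  utils::write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CE-optimization CSV: one row per transition x candidate CE
#'
#' @param method_table transition table with a `collision_energy` column.
#' @param path CSV path.
#' @export
write_ce_optimization <- function(method_table, path) {
  rows <- lapply(seq_len(nrow(method_table)), function(i) {
    ces <- ce_schedule(method_table$collision_energy[i])
    cbind(method_table[rep(i, length(ces)), , drop = FALSE],
          candidate_ce = ces)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write a mixture manifest TSV
#' @param mixtures data.frame from [assemble_mixtures()].
#' @param path TSV path.
#' @export
write_mixtures <- function(mixtures, path) .write_tsv(mixtures, path)

#' Validate a panel TSV
#'
#' Row-level invariant checks on a written panel file: selected entries must
#' be 6--40 residues long, carry 1--2 phosphosites on S/T/Y, and have a valid
#' enrichment route.
#'
#' @param path panel TSV path.
#' @return data.frame of violations (`row`, `problem`); zero rows when the
#'   file is clean.
#' @export
validate_panel_file <- function(path) {
  panel <- read_panel(path)
  problems <- list()
  flag <- function(i, msg) {
    problems[[length(problems) + 1L]] <<- data.frame(
      row = i, problem = msg, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(panel))) {
    if (panel$status[i] != "selected") next
    len <- nchar(panel$sequence[i])
    if (is.na(len) || len < 6L || len > 40L) {
      flag(i, sprintf("selected peptide length %s outside 6..40", len))
    }
    n_p <- lengths(regmatches(panel$modified_sequence[i],
                              gregexpr("\\(p[STY]\\)",
                                       panel$modified_sequence[i])))
    if (n_p < 1L || n_p > 2L) {
      flag(i, sprintf("phospho count %d outside 1..2", n_p))
    }
    if (!panel$enrichment_route[i] %in% c("IMAC", "pY", "IMACpY")) {
      flag(i, paste0("invalid enrichment route '",
                     panel$enrichment_route[i], "'"))
    }
  }
  if (length(problems) == 0L) {
    return(data.frame(row = integer(0), problem = character(0)))
  }
  do.call(rbind, problems)
}
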