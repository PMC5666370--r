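#' Read precursor sequences and processing annotations
#'
#' Reads a protein FASTA of precursors (wrapped lines are fine; a trailing
#' `*` stop character is stripped with a warning) and a named-column TSV of
#' processing annotations, and joins them into a precursor table.
#'
#' The annotation TSV needs columns `id`, `signal_end` and optionally
#' `propeptide_end` (0-based end indices of the signal peptide and spacer)
#' and `notes`. Every FASTA record must have an annotation row: signal
#' cleavage sites are required input, not predicted.
#'
#' @param fasta_file Path to the precursor FASTA.
#' @param annotation_file Path to the annotation TSV.
#' @return Tibble of validated precursor records (one per FASTA entry).
#' @export
read_precursors <- function(fasta_file, annotation_file) {
  seqs <- Biostrings::readAAStringSet(fasta_file)
  if (length(seqs) == 0) {
    stop("no sequences in FASTA file '", fasta_file, "'", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  raw <- unname(as.character(seqs))
  if (any(grepl("\\*$", raw))) {
    warning("stripped trailing '*' stop character from ",
            sum(grepl("\\*$", raw)), " sequence(s)", call. = FALSE)
    raw <- sub("\\*$", "", raw)
  }
  ann <- read_annotations(annotation_file)
  missing_ann <- setdiff(ids, ann$id)
  if (length(missing_ann) > 0) {
    stop("no annotation row for precursor(s): ",
         paste(missing_ann, collapse = ", "),
         " in '", annotation_file, "'", call. = FALSE)
  }
  ann <- ann[match(ids, ann$id), ]
  do.call(rbind, lapply(seq_along(ids), function(i) {
    precursor_record(
      id = ids[i],
      sequence = raw[i],
      signal_end = ann$signal_end[i],
      propeptide_end = ann$propeptide_end[i],
      source = if ("notes" %in% names(ann)) ann$notes[i] else NA_character_
    )
  }))
}

#' @rdname read_precursors
#' @export
read_annotations <- function(annotation_file) {
  ann <- utils::read.delim(annotation_file, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "signal_end") %in% names(ann))) {
    stop("annotation TSV '", annotation_file,
         "' must have named columns 'id' and 'signal_end'", call. = FALSE)
  }
  if (!"propeptide_end" %in% names(ann)) {
    ann$propeptide_end <- NA_integer_
  }
  tibble::as_tibble(ann)
}

#' Write a candidate table as TSV
#'
#' Columns mirror the internal candidate tibble (id, sequence, terminal
#' state, multimer, provenance, Hill formula, monoisotopic mass to 3
#' decimals). A header comment records the atomic-mass constant set so the
#' numbers are auditable.
#'
#' @param candidates Candidate tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_candidates <- function(candidates, file) {
  out <- candidates
  out$mass <- sprintf("%.3f", out$mass)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# mass constants: ", MASS_TABLE_VERSION), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read an observed-mass list (CSV or TSV)
#'
#' Expects named columns `mass` (neutral monoisotopic Da) and optionally
#' `rt`, `area`, `label`. Delimiter is inferred from the extension
#' (`.csv` = comma, otherwise tab).
#'
#' @param file Path.
#' @return Tibble as from [observed_masses()].
#' @export
read_observed_masses <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(file, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  if (!"mass" %in% names(df)) {
    stop("mass list '", file, "' must have a named 'mass' column",
         call. = FALSE)
  }
  observed_masses(
    mass = df$mass,
    rt = if ("rt" %in% names(df)) df$rt else NA_real_,
    area = if ("area" %in% names(df)) df$area else NA_real_,
    label = if ("label" %in% names(df)) df$label else NULL
  )
}

#' @rdname read_observed_masses
#' @param observed Tibble from [observed_masses()].
#' @export
write_observed_masses <- function(observed, file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  utils::write.table(observed, file, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read and write MGF peak lists
#'
#' Minimal Mascot Generic Format support: `BEGIN IONS`/`END IONS` blocks
#' with `TITLE`, `PEPMASS`, `CHARGE` and `RTINSECONDS` headers and
#' whitespace-separated m/z-intensity lines. Malformed lines raise an
#' error naming the file and line number.
#'
#' @param file Path to an MGF file.
#' @return `read_mgf()`: a named list of [peak_list()]s.
#' @export
read_mgf <- function(file) {
  lines <- readLines(file)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      title <- sprintf("spectrum%03d", length(out) + 1L)
      pepmass <- NA_real_
      charge <- NA_integer_
      rt <- NA_real_
      mz <- numeric()
      inten <- numeric()
      i <- i + 1L
      repeat {
        if (i > n) {
          stop("MGF '", file, "': unterminated BEGIN IONS block",
               call. = FALSE)
        }
        line <- trimws(lines[i])
        if (line == "END IONS") break
        if (grepl("^TITLE=", line)) {
          title <- sub("^TITLE=", "", line)
        } else if (grepl("^PEPMASS=", line)) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", line),
                                         "[[:space:]]+")[[1]][1])
        } else if (grepl("^CHARGE=", line)) {
          charge <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", line)))
        } else if (grepl("^RTINSECONDS=", line)) {
          rt <- as.numeric(sub("^RTINSECONDS=", "", line)) / 60
        } else if (grepl("=", line, fixed = TRUE) || line == "") {
          # other headers / blank lines ignored
        } else {
          fields <- strsplit(line, "[[:space:]]+")[[1]]
          vals <- suppressWarnings(as.numeric(fields))
          if (length(vals) < 1 || anyNA(vals[1])) {
            stop("MGF '", file, "' line ", i, ": cannot parse peak '",
                 line, "'", call. = FALSE)
          }
          mz <- c(mz, vals[1])
          inten <- c(inten, if (length(vals) >= 2) vals[2] else 1)
        }
        i <- i + 1L
      }
      out[[title]] <- peak_list(mz, inten, precursor_mz = pepmass,
                                precursor_z = charge, rt = rt,
                                title = title)
    }
    i <- i + 1L
  }
  out
}

#' @rdname read_mgf
#' @param peaklists Named list of [peak_list()]s.
#' @export
write_mgf <- function(peaklists, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(peaklists)) {
    pl <- peaklists[[nm]]
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", nm), con)
    if (!is.na(pl$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.6f", pl$precursor_mz), con)
    }
    if (!is.na(pl$precursor_z)) {
      writeLines(sprintf("CHARGE=%d+", pl$precursor_z), con)
    }
    if (!is.na(pl$rt)) {
      writeLines(sprintf("RTINSECONDS=%.2f", pl$rt * 60), con)
    }
    writeLines(sprintf("%.6f %.2f", pl$mz, pl$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(file)
}

#' Run configuration
#'
#' Every pipeline option with its default, serializable to YAML and back
#' unchanged. `tol_ppm`/`tol_da` are the strict precursor-mass matching
#' tolerances, `loose_da` the labelled loose tier, `frag_tol` the MS/MS
#' fragment tolerance in Da; the rule toggles mirror
#' [enumerate_mature_forms()] and [truncation_ladder()].
#'
#' @param ... Overrides of default fields (unknown names are an error).
#' @return Named list of configuration values.
#' @examples
#' default_config(tol_ppm = 5)$tol_ppm
#' @export
default_config <- function(...) {
  cfg <- list(
    tol_ppm = 10,
    tol_da = 0.02,
    loose_da = 0.1,
    frag_tol = 0.02,
    amidation = TRUE,
    des_k = TRUE,
    des_k_any = FALSE,
    dimer = TRUE,
    ladder = FALSE,
    min_length = 5L,
    seed = 1L,
    verbose = FALSE
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' @rdname default_config
#' @param file Path to a YAML config file.
#' @export
read_config <- function(file) {
  do.call(default_config, yaml::read_yaml(file))
}

#' @rdname default_config
#' @param config A configuration list.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}
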