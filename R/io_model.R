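## Domain types and readers/writers: germline FASTA, AIRR-style rearrangement
## TSV, 144-cell dinucleotide substitution CSV, DBS-78 catalog CSV, JSON report.
##
## Coordinate convention used throughout the package: 0-based, half-open,
## in UNGAPPED germline space. IMGT '.' gap columns carry no position number
## and never contribute to mutation calling.

NUCS <- c("A", "C", "G", "T")
DINUCS <- as.vector(t(outer(NUCS, NUCS, paste0)))  # alphabetical: AA AC ... TT

#' Construct a germline V allele
#'
#' A reference V-region nucleotide sequence together with its reading frame
#' and optional region annotation. The sequence may contain IMGT '.' gap
#' characters; these columns are excluded from all position arithmetic.
#'
#' @param name allele identifier, e.g. `"IGHV3-23*01"`.
#' @param sequence nucleotide string over `A,C,G,T` plus `'.'` gaps.
#' @param frame_offset integer 0-2: ungapped index of the first base of
#'   codon 1.
#' @param regions optional named list of half-open codon-position intervals,
#'   e.g. `list(FR1 = c(0, 25), CDR1 = c(25, 33), ...)`, ascending and
#'   non-overlapping.
#' @return an object of class `germline_allele` with precomputed
#'   ungapped sequence and ungapped-to-gapped coordinate map.
#' @export
germline_allele <- function(name, sequence, frame_offset = 0L, regions = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("allele '", name, "': empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(NUCS, "."))
  if (length(bad) > 0L) {
    stop("allele '", name, "': invalid character(s) in sequence: ",
         paste(bad, collapse = ", "))
  }
  keep <- chars != "."
  ungapped <- chars[keep]
  if (length(ungapped) < 3L) {
    stop("allele '", name, "': ungapped length must be >= 3")
  }
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  if (!is.null(regions)) {
    iv <- do.call(rbind, regions)
    if (ncol(iv) != 2L || any(iv[, 1] >= iv[, 2])) {
      stop("regions must be half-open intervals with start < end")
    }
    if (is.unsorted(as.vector(t(iv)), strictly = FALSE)) {
      stop("regions must be ascending and non-overlapping")
    }
  }
  structure(
    list(
      name = name,
      sequence = sequence,
      ungapped = paste(ungapped, collapse = ""),
      frame_offset = as.integer(frame_offset),
      regions = regions,
      # 0-based gapped column for each 0-based ungapped position
      map_u2g = which(keep) - 1L,
      length_ungapped = length(ungapped)
    ),
    class = "germline_allele"
  )
}

#' @export
print.germline_allele <- function(x, ...) {
  cat("<germline_allele>", x$name, "\n")
  cat("  length:", x$length_ungapped, "nt ungapped (",
      nchar(x$sequence), "aligned ), frame offset", x$frame_offset, "\n")
  if (!is.null(x$regions)) {
    cat("  regions:", paste(names(x$regions), collapse = " "), "\n")
  }
  invisible(x)
}

#' Read germline V alleles from FASTA
#'
#' @param path FASTA file; headers carry the allele name (first whitespace
#'   token).
#' @param config optional named list keyed by allele name, each entry a list
#'   with `frame_offset` and/or `regions` (see [germline_allele()]); such a
#'   list can be read from JSON with [read_allele_config()]. Alleles absent
#'   from the config get `frame_offset = 0` and no regions.
#' @return named list of `germline_allele` objects.
#' @export
read_germline_fasta <- function(path, config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  # BStringSet: accept any character at parse time, validate per allele below
  # so the error can name the offending record rather than a file offset.
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(structure(list(), names = character(0)))
  out <- list()
  for (i in seq_along(set)) {
    name <- strsplit(names(set)[[i]], "\\s+")[[1]][[1]]
    cfg <- if (!is.null(config)) config[[name]] else NULL
    out[[name]] <- germline_allele(
      name, as.character(set[[i]]),
      frame_offset = if (!is.null(cfg$frame_offset)) cfg$frame_offset else 0L,
      regions = cfg$regions
    )
  }
  out
}

#' Write germline alleles to FASTA
#' @param alleles list of `germline_allele`.
#' @param path output file.
#' @export
write_germline_fasta <- function(alleles, path) {
  lines <- unlist(lapply(alleles, function(a) c(paste0(">", a$name), a$sequence)))
  writeLines(lines, path)
  invisible(path)
}

#' Read allele frame/region configuration from JSON
#'
#' The configuration maps allele names to `frame_offset` and `regions`
#' entries. Region intervals are half-open codon-position pairs.
#' @param path JSON file.
#' @export
read_allele_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  lapply(cfg, function(entry) {
    if (!is.null(entry$regions)) {
      entry$regions <- lapply(entry$regions, as.integer)
    }
    entry
  })
}

REARRANGEMENT_REQUIRED <- c("sequence_id", "v_call", "sequence_alignment",
                            "germline_alignment", "cdr3")
REARRANGEMENT_OPTIONAL <- c("d_call", "j_call", "isotype")

#' Count mutated positions between aligned sequence and germline
#'
#' Positions are compared column-wise; columns where the germline carries an
#' IMGT '.' gap are excluded entirely, and columns where the observed base is
#' not one of A, C, G, T (e.g. `N` or `-`) are never counted as mutated.
#'
#' @param sequence_alignment,germline_alignment equal-length character
#'   vectors of gapped nucleotide strings.
#' @return integer vector of mutation counts.
#' @export
count_mutations <- function(sequence_alignment, germline_alignment) {
  stopifnot(length(sequence_alignment) == length(germline_alignment))
  mapply(function(s, g) {
    sc <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    gc <- strsplit(toupper(g), "", fixed = TRUE)[[1]]
    keep <- gc %in% NUCS  # drop germline gaps and non-base columns
    sum(sc[keep] %in% NUCS & sc[keep] != gc[keep])
  }, sequence_alignment, germline_alignment, USE.NAMES = FALSE)
}

#' Read AIRR-style rearrangement records from TSV
#'
#' Required columns: `sequence_id`, `v_call`, `sequence_alignment`,
#' `germline_alignment`, `cdr3`. Optional: `d_call`, `j_call`, `isotype`.
#' Rows with an empty `v_call` or `sequence_alignment` are dropped; the
#' number dropped is recorded in attribute `n_dropped` and reported via
#' `message()`. A `mutation_count` column is derived with
#' [count_mutations()] if not already present.
#'
#' @param path TSV file with header.
#' @return data.frame of retained records.
#' @export
read_rearrangements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(REARRANGEMENT_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in REARRANGEMENT_OPTIONAL) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  ok <- nzchar(df$v_call) & !is.na(df$v_call) &
    nzchar(df$sequence_alignment) & !is.na(df$sequence_alignment)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(n_dropped, " record(s) dropped (missing v_call or alignment)")
  }
  df <- df[ok, , drop = FALSE]
  bad_len <- nchar(df$sequence_alignment) != nchar(df$germline_alignment)
  if (any(bad_len)) {
    stop("alignment length mismatch for sequence_id: ",
         paste(df$sequence_id[bad_len], collapse = ", "))
  }
  if ("mutation_count" %in% names(df)) {
    df$mutation_count <- as.integer(df$mutation_count)
  } else {
    df$mutation_count <- count_mutations(df$sequence_alignment,
                                         df$germline_alignment)
  }
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Write rearrangement records to TSV
#' @param records data.frame of records.
#' @param path output file.
#' @export
write_rearrangements <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct an empty dinucleotide substitution table
#'
#' A 16 x 16 numeric matrix (reference dinucleotide rows, mutated
#' dinucleotide columns) whose 144 legal cells — both bases substituted —
#' are 0 and whose illegal cells are `NA`. Counts may become fractional
#' after in-silico correction.
#' @return matrix of class `dinuc_table`.
#' @export
dinuc_table <- function() {
  m <- matrix(NA_real_, 16L, 16L, dimnames = list(DINUCS, DINUCS))
  for (ref in DINUCS) {
    for (alt in DINUCS) {
      if (substr(alt, 1, 1) != substr(ref, 1, 1) &&
          substr(alt, 2, 2) != substr(ref, 2, 2)) {
        m[ref, alt] <- 0
      }
    }
  }
  class(m) <- c("dinuc_table", "matrix", "array")
  m
}

#' Write a dinucleotide substitution table to CSV
#'
#' 16 reference rows; per row the 9 legal outcome columns hold counts and
#' the illegal columns are left empty.
#' @param table a `dinuc_table`.
#' @param path output file.
#' @export
write_substitution_table <- function(table, path) {
  stopifnot(inherits(table, "dinuc_table"))
  m <- unclass(table)
  utils::write.csv(as.data.frame(m), path, na = "", row.names = TRUE)
  invisible(path)
}

#' Read a dinucleotide substitution table from CSV
#' @param path CSV written by [write_substitution_table()].
#' @return a `dinuc_table`.
#' @export
read_substitution_table <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!identical(rownames(m), DINUCS) || !identical(colnames(m), DINUCS)) {
    stop("substitution table must have the 16 dinucleotides as rows and columns")
  }
  out <- dinuc_table()
  legal <- !is.na(unclass(out))
  out[legal] <- ifelse(is.na(m[legal]), 0, m[legal])
  out
}

#' Read a DBS-78 signature catalog from CSV
#'
#' First column: class labels (e.g. `"AC>CA"`); remaining column(s): values.
#' @param path CSV file.
#' @return named numeric vector (single signature) or matrix with one
#'   column per signature, rows ordered as [dbs78_classes()].
#' @export
read_dbs_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- df[[1]]
  classes <- dbs78_classes()
  if (!setequal(labels, classes) || length(labels) != 78L) {
    stop("DBS catalog must contain exactly the 78 canonical classes")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- labels
  vals <- vals[classes, , drop = FALSE]
  if (ncol(vals) == 1L) {
    out <- as.numeric(vals[, 1]); names(out) <- classes
    out
  } else {
    vals
  }
}

#' Write a DBS-78 catalog to CSV
#' @param catalog named numeric vector over the 78 classes.
#' @param path output file.
#' @export
write_dbs_catalog <- function(catalog, path) {
  stopifnot(length(catalog) == 78L)
  utils::write.csv(data.frame(class = names(catalog), value = as.numeric(catalog)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report to JSON
#'
#' Round-trips losslessly via [read_report()] (numbers at full precision).
#' @param report a list.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(strip_s3(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

## drop package-specific S3 classes so jsonlite sees plain lists/frames
strip_s3 <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    x <- lapply(x, strip_s3)
    class(x) <- NULL
    return(x)
  }
  if (is.matrix(x)) class(x) <- NULL
  x
}

#' Read an analysis report from JSON
#' @param path JSON file written by [write_report()].
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
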