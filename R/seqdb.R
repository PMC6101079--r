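#' Read a protein FASTA database into a tibble
#'
#' Parses a FASTA file of amino-acid sequences. The accession is the first
#' whitespace-delimited token of the header line; the remainder is kept as the
#' description. Sequence lines are concatenated, whitespace-stripped and
#' uppercased. The 20 standard residues plus the ambiguity letters B, Z, X, U,
#' O are tolerated.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `description`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "PEPTIDE"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    return(tibble(
      accession = character(), description = character(),
      sequence = character()
    ))
  }
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers), ""
  )
  sequence <- unname(toupper(gsub("\\s", "", as.character(aa))))
  if (any(!nzchar(sequence))) {
    bad <- accession[!nzchar(sequence)][1L]
    stop("record with empty sequence: ", bad, call. = FALSE)
  }
  dup <- accession[duplicated(accession)]
  if (length(dup)) {
    stop("duplicate accession in FASTA: ", dup[1L], call. = FALSE)
  }
  tibble(accession = accession, description = description, sequence = sequence)
}

#' Write a protein tibble to FASTA
#'
#' Inverse of [read_fasta()]; sequences are wrapped at 60 characters per line.
#'
#' @param records Tibble with columns `accession`, `description`, `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  check_protein_records(records)
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- ifelse(nzchar(records$description),
    paste(records$accession, records$description),
    records$accession
  )
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

check_protein_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("accession", "sequence")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("records lack column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(records[["description"]])) records$description <- ""
  if (any(!nzchar(records$sequence))) {
    stop("record with empty sequence: ",
      records$accession[!nzchar(records$sequence)][1L],
      call. = FALSE
    )
  }
  dup <- records$accession[duplicated(records$accession)]
  if (length(dup)) stop("duplicate accession: ", dup[1L], call. = FALSE)
  invisible(records)
}

#' Randomly shuffle an amino-acid sequence
#'
#' Draws a uniformly random permutation of the residues (Fisher-Yates, via
#' `sample()`): the output has the same length and the same residue multiset
#' as the input. Used to generate decoy sequences whose composition matches
#' the target database.
#'
#' @param sequence Non-empty amino-acid string.
#' @return The shuffled string.
#' @examples
#' set.seed(1)
#' shuffle_sequence("PEPTIDE")
#' @export
shuffle_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("cannot shuffle an empty sequence", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  paste(sample(chars), collapse = "")
}

#' Build a concatenated target-decoy database
#'
#' Appends one per-sequence shuffled decoy per target protein. Decoys take the
#' accession `paste0(decoy_prefix, accession)`; targets are returned unchanged
#' first, so the output has exactly twice as many records as the input.
#' Decoy labeling is by case-sensitive accession prefix (see [is_decoy()]).
#'
#' @param records Target protein tibble (see [read_fasta()]).
#' @param seed Integer seed making the shuffles reproducible.
#' @param decoy_prefix Accession prefix marking decoys. Default `"DECOY_"`.
#' @return A tibble of `2 * nrow(records)` protein records.
#' @examples
#' db <- tibble::tibble(
#'   accession = "P1", description = "", sequence = "PEPTIDESEQ"
#' )
#' build_target_decoy_db(db, seed = 1)
#' @export
build_target_decoy_db <- function(records, seed, decoy_prefix = "DECOY_") {
  check_protein_records(records)
  stopifnot(is.character(decoy_prefix), nzchar(decoy_prefix))
  if (any(startsWith(records$accession, decoy_prefix))) {
    bad <- records$accession[startsWith(records$accession, decoy_prefix)][1L]
    stop(
      "target accession already carries the decoy prefix: ", bad,
      call. = FALSE
    )
  }
  if (nrow(records) == 0L) {
    return(records[, c("accession", "description", "sequence")])
  }
  if (is.null(records[["description"]])) records$description <- ""
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, globalenv()),
      add = TRUE
    )
    set.seed(seed)
    code
  }
  decoys <- withr_seed(vapply(records$sequence, shuffle_sequence, character(1),
    USE.NAMES = FALSE
  ))
  dplyr::bind_rows(
    tibble(
      accession = records$accession,
      description = records$description,
      sequence = records$sequence
    ),
    tibble(
      accession = paste0(decoy_prefix, records$accession),
      description = records$description,
      sequence = decoys
    )
  )
}

#' Is an accession a decoy?
#'
#' Case-sensitive prefix test; vectorised over `accession`.
#'
#' @param accession Character vector of accessions.
#' @param decoy_prefix Decoy accession prefix. Default `"DECOY_"`.
#' @return Logical vector.
#' @examples
#' is_decoy(c("DECOY_P1", "P1"))
#' @export
is_decoy <- function(accession, decoy_prefix = "DECOY_") {
  startsWith(accession, decoy_prefix)
}
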