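#' Build a stretch table
#'
#' A *stretch* is a run of exactly `gamma` residues taken from the start or
#' end of a secondary-structure element (alpha-helix or beta-sheet).
#' Stretch tables are plain tibbles with columns `protein_id`,
#' `element_kind` (`"helix"` or `"strand"`), `terminus` (`"start"` or
#' `"end"`), `sequence` (a `gamma`-letter string over the canonical
#' alphabet) and `element_length` (length of the source element).
#'
#' @param sequence Character vector of fixed-length residue strings.
#' @param protein_id,element_kind,terminus,element_length Recycled metadata
#'   columns; `element_length` defaults to the stretch length itself.
#' @returns A tibble with the five stretch columns, validated.
#' @export
#' @examples
#' stretch_table(c("ACDEF", "LLLLL"))
stretch_table <- function(sequence,
                          protein_id = "synthetic",
                          element_kind = "helix",
                          terminus = "start",
                          element_length = NULL) {
  gamma <- unique(nchar(sequence))
  if (length(sequence) > 0 && length(gamma) != 1) {
    stop("all stretch sequences must have the same length", call. = FALSE)
  }
  if (is.null(element_length)) {
    element_length <- if (length(sequence)) gamma else integer()
  }
  tbl <- tibble::tibble(
    protein_id = as.character(protein_id),
    element_kind = as.character(element_kind),
    terminus = as.character(terminus),
    sequence = as.character(sequence),
    element_length = as.integer(element_length)
  )
  validate_stretch_table(tbl)
  tbl
}

validate_stretch_table <- function(tbl) {
  need <- c("protein_id", "element_kind", "terminus", "sequence", "element_length")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("stretch table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tbl) == 0) return(invisible(tbl))
  if (length(unique(nchar(tbl$sequence))) != 1) {
    stop("stretch sequences have unequal lengths", call. = FALSE)
  }
  if (any(tbl$element_length < nchar(tbl$sequence))) {
    stop("element_length must be >= the stretch length", call. = FALSE)
  }
  aa_index(unique(seq_chars(paste(tbl$sequence, collapse = ""))))
  invisible(tbl)
}

#' One-hot spin encoding of residue stretches
#'
#' Each residue position `gamma` occupies a block of 20 consecutive visible
#' units; the unit at the residue's alphabetical index is `+1` and the
#' other 19 are `-1`, so a stretch of `Gamma` residues becomes a spin
#' vector of `N_v = 20 * Gamma` entries and every block sums to `-18`.
#'
#' @param stretches A stretch table (see [stretch_table()]) or a character
#'   vector of equal-length sequences.
#' @returns An integer matrix (`n x 20*Gamma`) of `+1/-1` values with
#'   attribute `gamma`; rows correspond to rows of the input.
#' @seealso [decode_one_hot()] for the exact inverse.
#' @export
#' @examples
#' v <- encode_one_hot(c("AC", "YY"))
#' decode_one_hot(v)
encode_one_hot <- function(stretches) {
  seqs <- if (is.character(stretches)) stretches else {
    validate_stretch_table(stretches)
    stretches$sequence
  }
  n <- length(seqs)
  gamma <- if (n) nchar(seqs[[1]]) else 0L
  if (n && any(nchar(seqs) != gamma)) {
    stop("all sequences must have equal length", call. = FALSE)
  }
  v <- matrix(-1L, nrow = n, ncol = 20L * gamma)
  if (n) {
    k <- aa_index(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE))
    pos <- visible_index(rep(seq_len(gamma), times = n),
                         k) # block index cycles fastest within each sequence
    v[cbind(rep(seq_len(n), each = gamma), pos)] <- 1L
  }
  attr(v, "gamma") <- as.integer(gamma)
  v
}

#' Decode spin vectors back to residue strings
#'
#' @param v A spin matrix (or single vector) as produced by
#'   [encode_one_hot()]: one `+1` per 20-unit block.
#' @returns Character vector of residue sequences.
#' @export
decode_one_hot <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  if (ncol(v) %% 20 != 0) stop("ncol(v) must be divisible by 20", call. = FALSE)
  gamma <- ncol(v) %/% 20L
  if (nrow(v) == 0) return(character())
  out <- vapply(seq_len(nrow(v)), function(r) {
    blocks <- matrix(v[r, ], nrow = 20L)
    k <- apply(blocks == 1L, 2, which)
    if (!is.integer(k) || length(k) != gamma) {
      stop("row ", r, " is not a valid one-hot spin vector", call. = FALSE)
    }
    paste(aa_alphabet[k], collapse = "")
  }, character(1))
  out
}

#' Random train/validation split
#'
#' Uniform random partition of sample indices, reproducible from `seed`.
#' The train size is `round(fraction * n)`, clamped so both parts are
#' non-empty.
#'
#' @param samples A stretch table, spin matrix, or anything with rows
#'   (a plain vector is split by element).
#' @param fraction Proportion assigned to the training part (default 0.8).
#' @param seed Integer seed controlling the partition.
#' @returns A list with elements `train`, `valid` (same type as the input),
#'   `train_idx`, `valid_idx`, `fraction` and `seed`.
#' @export
split_train_valid <- function(samples, fraction = 0.8, seed = 1L) {
  n <- if (is.null(dim(samples))) length(samples) else nrow(samples)
  if (n < 2) stop("need at least 2 samples to split", call. = FALSE)
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0,1)", call. = FALSE)
  n_train <- min(max(round(fraction * n), 1L), n - 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train_idx <- sort(sample.int(n, n_train))
  valid_idx <- setdiff(seq_len(n), train_idx)
  take <- function(x, i) if (is.null(dim(x))) x[i] else x[i, , drop = FALSE]
  list(train = take(samples, train_idx),
       valid = take(samples, valid_idx),
       train_idx = train_idx, valid_idx = valid_idx,
       fraction = fraction, seed = as.integer(seed))
}

# Save/restore the global RNG state so seeded helpers do not clobber the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Read / write stretch tables as TSV
#'
#' Plain tab-separated files with header
#' `protein_id element_kind terminus sequence element_length`
#' (`element_length` is optional on input and defaults to the stretch
#' length).
#'
#' @param path File path.
#' @param stretches A stretch table.
#' @returns `read_stretches()` returns a validated stretch table;
#'   `write_stretches()` returns `stretches` invisibly.
#' @export
read_stretches <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!"element_length" %in% names(tbl)) {
    tbl$element_length <- nchar(tbl$sequence)
  }
  tbl$element_length <- as.integer(tbl$element_length)
  validate_stretch_table(tbl)
  tbl[c("protein_id", "element_kind", "terminus", "sequence", "element_length")]
}

#' @rdname read_stretches
#' @export
write_stretches <- function(stretches, path) {
  validate_stretch_table(stretches)
  readr::write_tsv(stretches, path)
  invisible(stretches)
}
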