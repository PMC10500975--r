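#' Parse a classic DSSP output file
#'
#' Reads the column-formatted `.dssp` dialect: everything up to the line
#' whose header starts with `#  RESIDUE` is treated as preamble, then each
#' record carries the chain id (column 12), the one-letter amino acid
#' (column 14) and the secondary-structure code (column 17).  A `!` in the
#' amino-acid column is a chain break and starts a new segment, so no
#' secondary-structure element can span a break.  Lowercase amino-acid
#' letters (DSSP's disulfide-bonded cysteines) are mapped to `C`; any other
#' code, including unknown secondary-structure letters, is kept verbatim.
#'
#' @param path Path to a DSSP file.
#' @param protein_id Identifier recorded for the file; defaults to the file
#'   name without extension.
#' @returns A tibble with one row per contiguous segment: `protein_id`,
#'   `chain`, `segment`, `sequence`, `ss` (equal-length strings of residues
#'   and per-residue secondary-structure codes).
#' @export
parse_dssp <- function(path, protein_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty DSSP file: ", path, call. = FALSE)
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(hdr) == 0) {
    stop("not a classic DSSP file (no '#  RESIDUE' header line): ", path,
         call. = FALSE)
  }
  body <- lines[seq(hdr[1] + 1L, length.out = length(lines) - hdr[1])]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stop("DSSP file has no residue records: ", path, call. = FALSE)
  short <- which(nchar(body) < 17)
  # chain-break rows are legitimately short; anything else is truncated
  aa_raw <- substr(body, 14, 14)
  bad <- short[aa_raw[short] != "!" | nchar(body[short]) < 14]
  if (length(bad)) {
    stop("truncated DSSP record at line ", hdr[1] + bad[1], " of ", path,
         call. = FALSE)
  }

  chain <- substr(body, 12, 12)
  aa <- aa_raw
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "-"
  is_break <- aa == "!"
  # disulfide cysteines are reported as lowercase letters
  lower <- aa %in% letters
  aa[lower] <- "C"

  seg_id <- cumsum(is_break | c(TRUE, chain[-1] != chain[-length(chain)]))
  keep <- !is_break
  if (!any(keep)) stop("DSSP file contains only chain breaks: ", path, call. = FALSE)
  tibble::tibble(chain = chain[keep], seg = seg_id[keep],
                 aa = aa[keep], ss = ss[keep]) |>
    dplyr::group_by(.data$chain, .data$seg) |>
    dplyr::summarise(sequence = paste(.data$aa, collapse = ""),
                     ss = paste(.data$ss, collapse = ""), .groups = "drop") |>
    dplyr::arrange(.data$seg) |>
    dplyr::transmute(protein_id = protein_id, chain = .data$chain,
                     segment = dplyr::row_number(),
                     sequence = .data$sequence, ss = .data$ss)
}

#' Extract boundary stretches from secondary-structure annotation
#'
#' Finds every maximal run of the element's DSSP code (`H` for alpha-helix,
#' `E` for beta-strand; the stricter one-code reading) of length at least
#' `gamma` within each annotated segment, and returns the first (`terminus
#' = "start"`) or last (`"end"`) `gamma` residues of each run in N-to-C
#' order.  Runs shorter than `gamma` yield nothing; for a run of exactly
#' `gamma` residues the start and end stretches coincide.  Stretches
#' containing a non-canonical residue (e.g. `X`) are dropped and counted in
#' the `n_rejected` attribute.
#'
#' @param annotation A tibble as returned by [parse_dssp()] (columns
#'   `protein_id`, `sequence`, `ss`).
#' @param element_kind `"helix"` (code `H`) or `"strand"` (code `E`).
#' @param terminus `"start"` or `"end"`.
#' @param gamma Stretch length (default 5).
#' @returns A stretch table; attribute `n_rejected` counts stretches
#'   dropped for non-canonical residues.
#' @export
extract_stretches <- function(annotation, element_kind = c("helix", "strand"),
                              terminus = c("start", "end"), gamma = 5L) {
  element_kind <- match.arg(element_kind)
  terminus <- match.arg(terminus)
  gamma <- as.integer(gamma)
  if (gamma < 1) stop("gamma must be >= 1", call. = FALSE)
  code <- switch(element_kind, helix = "H", strand = "E")

  rows <- purrr::pmap(
    list(annotation$protein_id, annotation$sequence, annotation$ss),
    function(pid, sq, ss) {
      r <- rle(seq_chars(ss) == code)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ok <- r$values & r$lengths >= gamma
      if (!any(ok)) return(NULL)
      from <- if (terminus == "start") starts[ok] else ends[ok] - gamma + 1L
      tibble::tibble(protein_id = pid,
                     sequence = substring(sq, from, from + gamma - 1L),
                     element_length = r$lengths[ok])
    })
  tbl <- dplyr::bind_rows(rows)
  if (is.null(tbl) || nrow(tbl) == 0) {
    out <- stretch_table(character(), element_kind = element_kind,
                         terminus = terminus)
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  canon <- !grepl(paste0("[^", paste(aa_alphabet, collapse = ""), "]"),
                  tbl$sequence)
  out <- stretch_table(tbl$sequence[canon],
                       protein_id = tbl$protein_id[canon],
                       element_kind = element_kind, terminus = terminus,
                       element_length = tbl$element_length[canon])
  attr(out, "n_rejected") <- sum(!canon)
  out
}
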