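# Hand-built DSSP fixtures written to temp files at test time.

# Minimal classic-format DSSP text: preamble, header, one record per row.
# rows: list of list(num, chain, aa, ss); aa == "!" makes a break row.
write_dssp_fixture <- function(rows, path = tempfile(fileext = ".dssp")) {
  pre <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE  synthetic fixture",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  fmt <- function(r) {
    if (r$aa == "!") {
      sprintf("%5d        !", r$num)
    } else {
      # columns: 12 = chain, 14 = aa, 17 = ss; DSSP writes coil as blank
      ss <- if (r$ss %in% c("C", "-")) " " else r$ss
      sprintf("%5d %4d %s %s  %s", r$num, r$num, r$chain, r$aa, ss)
    }
  }
  writeLines(c(pre, vapply(rows, fmt, character(1))), path)
  path
}

# convenience: one chain from sequence + ss strings
dssp_rows <- function(seq, ss, chain = "A", start = 1L) {
  lapply(seq_along(seq_chars_t(seq)), function(i) {
    list(num = start + i - 1L, chain = chain,
         aa = substr(seq, i, i), ss = substr(ss, i, i))
  })
}

seq_chars_t <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

break_row <- function(num) list(num = num, chain = " ", aa = "!", ss = " ")
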