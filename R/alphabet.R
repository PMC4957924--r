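## Shared alphabet constants.  The scoring alphabet has 21 symbols: the 20
## standard amino acids plus '-' ("blank"), which marks positions that fall
## beyond a protein terminus in an 11-mer window.

#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @keywords internal
AA21 <- c(AA20, "-")

## Flank positions of an 11-mer window relative to the central pY:
## -5..-1 and +1..+5 (the centre itself is always Y and carries no signal).
#' @keywords internal
FLANK_POSITIONS <- c(-5:-1, 1:5)

#' @keywords internal
WINDOW_WIDTH <- 11L

#' @keywords internal
CENTER_OFFSET <- 6L

## Split windows into a character matrix of their 10 flank symbols
## (columns ordered -5..-1, +1..+5; centre column dropped).
#' @keywords internal
flank_matrix <- function(peptides) {
  stopifnot(all(nchar(peptides) == WINDOW_WIDTH))
  m <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
              ncol = WINDOW_WIDTH, byrow = TRUE)
  m[, -CENTER_OFFSET, drop = FALSE]
}
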