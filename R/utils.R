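`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter codes in alphabetical order, optionally
#' followed by the gap character.
#'
#' @param gap include `"-"` as the final state (default `TRUE`).
#' @return character vector of states.
#' @export
aa_alphabet <- function(gap = TRUE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (gap) c(aa, "-") else aa
}

# Gap state index of an alphabet (0 if no gap state), as used by the C++ core.
gap_state_of <- function(alphabet) {
  g <- match("-", alphabet)
  if (is.na(g)) 0L else g
}

stop_coevppi <- function(msg, class, ...) {
  stop(structure(class = c(class, "coevppi_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
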