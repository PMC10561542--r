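# Stimulus set construction for the CVC syllable repetition task.

#' Build the CVC stimulus set
#'
#' Crosses initial consonants with vowels, pairing each initial consonant
#' with a fixed final consonant, to produce the consonant-vowel-consonant
#' (CVC) syllable inventory of the repetition task. With the defaults this
#' yields the canonical 12-syllable set built from four plosive/affricate
#' consonants (b, d, g, j) and three vowels (ae, i, u), with the pairing
#' b-g, g-b, d-j, j-d. Consonant-pair labels are order sensitive: "b-g"
#' (initial b, final g) and "g-b" are distinct classes.
#'
#' @param consonants character vector of initial consonants.
#' @param vowels character vector of vowels.
#' @param pairing named character vector mapping each initial consonant to
#'   its final consonant; names must cover `consonants`.
#' @return an object of class `stimulus_set`: a list with
#'   \item{syllables}{data.frame with columns `syllable`, `consonant_pair`,
#'     `vowel`, `initial`, `final`}
#'   \item{consonant_pairs}{character vector of order-sensitive pair labels}
#'   \item{vowels}{character vector of vowel labels}
#' @examples
#' ss <- generate_stimulus_set()
#' nrow(ss$syllables)      # 12
#' ss$consonant_pairs      # "b-g" "d-j" "g-b" "j-d"
#' @export
generate_stimulus_set <- function(consonants = c("b", "d", "g", "j"),
                                  vowels = c("ae", "i", "u"),
                                  pairing = c(b = "g", d = "j", g = "b", j = "d")) {
  stopifnot(length(consonants) >= 1L, length(vowels) >= 1L)
  if (!all(consonants %in% names(pairing))) {
    stop("`pairing` must name a final consonant for every initial consonant")
  }
  grid <- expand.grid(initial = consonants, vowel = vowels,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(match(grid$initial, consonants), match(grid$vowel, vowels)), ]
  grid$final <- unname(pairing[grid$initial])
  grid$syllable <- paste0(grid$initial, grid$vowel, grid$final)
  grid$consonant_pair <- paste0(grid$initial, "-", grid$final)
  if (anyDuplicated(grid$syllable)) stop("syllable labels are not unique")
  rownames(grid) <- NULL
  out <- list(
    syllables = grid[, c("syllable", "consonant_pair", "vowel", "initial", "final")],
    consonant_pairs = unique(grid$consonant_pair),
    vowels = vowels
  )
  class(out) <- "stimulus_set"
  out
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("CVC stimulus set:", nrow(x$syllables), "syllables,",
      length(x$consonant_pairs), "consonant pairs,",
      length(x$vowels), "vowels\n")
  print(x$syllables)
  invisible(x)
}
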