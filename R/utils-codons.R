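.BASES <- c("A", "C", "G", "T")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.allCodons <- function() {
  g <- expand.grid(b3 = .BASES, b2 = .BASES, b1 = .BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' The 61 sense codons
#'
#' @param alphabet `"DNA"` (default) or `"RNA"`
#' @return character vector of the 61 non-stop codons, in alphabetical order
#' @examples
#' head(senseCodons("RNA"))
#' @export
senseCodons <- function(alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  x <- sort(setdiff(.allCodons(), .STOP_CODONS))
  if (alphabet == "RNA") codonToRna(x) else x
}

#' Translate codon labels between DNA and RNA alphabets
#'
#' Codon identities are matched against DNA coding sequences internally;
#' user-facing tables report codons in the RNA alphabet (UUU rather than
#' TTT). These two helpers are the fixed bijection applied at that boundary.
#'
#' @param x character vector of codons
#' @return `x` with T<->U exchanged
#' @examples
#' codonToRna("TTT"); codonToDna("AAA")
#' @export
codonToRna <- function(x) chartr("Tt", "Uu", x)

#' @rdname codonToRna
#' @export
codonToDna <- function(x) chartr("Uu", "Tt", x)

.isSenseCodon <- function(x) codonToDna(toupper(x)) %in% senseCodons("DNA")
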