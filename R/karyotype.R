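#' Karyotype model for translocated-chromosome size prediction
#'
#' Each parental chromosome is broken once; a translocant joins the left
#' fragment (everything left of the break) of one chromosome to the right
#' fragment of another.  The pairing must be a perfect matching: every left
#' and every right fragment used exactly once.  Junction-scale indels (< 10
#' bp) are invisible at kb resolution, so translocated sizes are exact
#' fragment sums and total material is conserved.
#'
#' @param chromosomes data.frame with columns \code{name}, \code{lengthKb},
#'   \code{breakKb} (0 < break < length).
#' @param pairing data.frame with columns \code{name} (translocant name),
#'   \code{leftOf}, \code{rightOf} (parental chromosome names).
#' @return object of class \code{"karyotypeModel"}.
#' @export
karyotypeModel <- function(chromosomes, pairing) {
  need <- c("name", "lengthKb", "breakKb")
  if (!all(need %in% names(chromosomes)))
    stop("chromosomes needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(c("name", "leftOf", "rightOf") %in% names(pairing)))
    stop("pairing needs columns name, leftOf, rightOf", call. = FALSE)
  if (any(chromosomes$breakKb <= 0 | chromosomes$breakKb >= chromosomes$lengthKb))
    stop("break positions must satisfy 0 < break < length", call. = FALSE)
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome names", call. = FALSE)
  if (!setequal(pairing$leftOf, chromosomes$name) ||
      anyDuplicated(pairing$leftOf) ||
      !setequal(pairing$rightOf, chromosomes$name) ||
      anyDuplicated(pairing$rightOf))
    stop("unmatched fragment: pairing must use every left and right fragment exactly once",
         call. = FALSE)
  structure(list(chromosomes = chromosomes, pairing = pairing),
            class = "karyotypeModel")
}

#' Predicted translocated-chromosome sizes
#'
#' @param model a [karyotypeModel()].
#' @return data.frame with columns \code{name} and \code{sizeKb}; sizes sum
#'   to the total parental length.
#' @examples
#' m <- karyotypeModel(
#'   data.frame(name = c("III", "XV"), lengthKb = c(316, 1091),
#'              breakKb = c(200, 695)),
#'   data.frame(name = c("tIII/XV", "tXV/III"),
#'              leftOf = c("III", "XV"), rightOf = c("XV", "III")))
#' translocatedSizes(m)   # 596 and 811 kb
#' @export
translocatedSizes <- function(model) {
  stopifnot(inherits(model, "karyotypeModel"))
  ch <- model$chromosomes
  leftLen <- stats::setNames(ch$breakKb, ch$name)
  rightLen <- stats::setNames(ch$lengthKb - ch$breakKb, ch$name)
  data.frame(name = model$pairing$name,
             sizeKb = unname(leftLen[model$pairing$leftOf] +
                             rightLen[model$pairing$rightOf]),
             stringsAsFactors = FALSE)
}
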