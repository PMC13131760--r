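#' Consonant and vowel inventory of the VCV task
#'
#' The closed-set identification task uses 13 consonants presented in
#' vowel-consonant-vowel (VCV) context, plus an explicit "other" response
#' button. Canonical labels are ASCII (`"sh"` for the postalveolar fricative,
#' `"a"` for the open back vowel); IPA spellings are accepted wherever labels
#' are read and mapped onto the canonical set.
#'
#' @return `qvcv_consonants()` returns the 13 canonical consonant labels;
#'   `qvcv_vowels()` the 3 vowel-context labels; `qvcv_other_label()` the
#'   label used for "other"/"???" responses.
#' @export
qvcv_consonants <- function() {
  c("b", "d", "g", "p", "t", "k", "v", "z", "f", "s", "sh", "m", "n")
}

#' @rdname qvcv_consonants
#' @export
qvcv_vowels <- function() c("a", "i", "u")

#' @rdname qvcv_consonants
#' @export
qvcv_other_label <- function() "other"

# IPA / legacy aliases accepted on input; "???" is an alternate label for the "other" button.
.consonant_aliases <- c("ʃ" = "sh")
.vowel_aliases <- c("ɑ" = "a")
.other_aliases <- c("other" = "other", "???" = "other", "OTHER" = "other")

#' Normalize consonant, vowel and response labels
#'
#' Maps IPA aliases onto the canonical ASCII label set and validates
#' membership. `normalize_response()` additionally accepts the
#' "other"/"???" button.
#'
#' @param x character vector of labels.
#' @return character vector of canonical labels.
#' @examples
#' normalize_consonant(c("b", "ʃ"))
#' normalize_response("???")
#' @export
normalize_consonant <- function(x) {
  x <- as.character(x)
  hit <- x %in% names(.consonant_aliases)
  x[hit] <- .consonant_aliases[x[hit]]
  bad <- !(x %in% qvcv_consonants())
  if (any(bad)) {
    stop("unknown consonant label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname normalize_consonant
#' @export
normalize_vowel <- function(x) {
  x <- as.character(x)
  hit <- x %in% names(.vowel_aliases)
  x[hit] <- .vowel_aliases[x[hit]]
  bad <- !(x %in% qvcv_vowels())
  if (any(bad)) {
    stop("unknown vowel label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname normalize_consonant
#' @export
normalize_response <- function(x) {
  x <- as.character(x)
  hit <- x %in% names(.other_aliases)
  x[hit] <- .other_aliases[x[hit]]
  cons <- x != qvcv_other_label()
  x[cons] <- normalize_consonant(x[cons])
  x
}

#' Articulatory features of the task consonants
#'
#' Voicing, place and manner of articulation for the 13 consonants, used by
#' the simulator to build confusion kernels (errors fall preferentially on
#' articulatorily similar consonants).
#'
#' @return data frame with columns `consonant`, `voiced` (0/1), `place`
#'   (`lab`, `alv`, `pal`, `vel`) and `manner` (`stop`, `fric`, `nas`).
#' @export
consonant_features <- function() {
  data.frame(
    consonant = qvcv_consonants(),
    voiced = c(1, 1, 1, 0, 0, 0, 1, 1, 0, 0, 0, 1, 1),
    place  = c("lab", "alv", "vel", "lab", "alv", "vel",
               "lab", "alv", "lab", "alv", "pal", "lab", "alv"),
    manner = c("stop", "stop", "stop", "stop", "stop", "stop",
               "fric", "fric", "fric", "fric", "fric", "nas", "nas"),
    stringsAsFactors = FALSE
  )
}

#' Articulatory distance between consonants
#'
#' Weighted Hamming distance over the (voicing, place, manner) features.
#' Setting a weight to zero makes that cue uninformative, e.g. a listener who
#' has lost the voicing cue confuses /b/-/p/ as readily as /b/-/b/ would
#' allow.
#'
#' @param weights named numeric vector with elements `voicing`, `place`,
#'   `manner`.
#' @return symmetric 13 x 13 matrix of distances, dimnames = consonants.
#' @export
consonant_distance <- function(weights = c(voicing = 1, place = 1, manner = 2)) {
  stopifnot(all(c("voicing", "place", "manner") %in% names(weights)),
            all(weights >= 0))
  f <- consonant_features()
  n <- nrow(f)
  d <- matrix(0, n, n, dimnames = list(f$consonant, f$consonant))
  for (i in seq_len(n)) {
    d[i, ] <- weights[["voicing"]] * (f$voiced != f$voiced[i]) +
      weights[["place"]] * (f$place != f$place[i]) +
      weights[["manner"]] * (f$manner != f$manner[i])
  }
  d
}
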