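#' Cause-of-death classes
#'
#' The six mutually exclusive classes the correction pipeline operates on:
#' breast cancer, other specified cancers, incomplete/unspecified cancer
#' diagnoses, ill-defined causes, other specified natural causes, and
#' external (non-natural) causes.
#'
#' @export
CAUSE_CLASSES <- c("BREAST", "OTHER_DEFINED_CANCER", "INCOMPLETE_CANCER",
                   "ILL_DEFINED", "OTHER_DEFINED_NATURAL", "NON_NATURAL")

# ICD-10 roots counted as incomplete/unspecified cancer diagnosis;
# the ICD-9 counterpart is the range 195-199.
ICD10_INCOMPLETE <- c("C76", "C77", "C78", "C79", "C80", "C97")

decade_of <- function(year) 10L * (as.integer(year) %/% 10L)

#' Classify an underlying cause-of-death code
#'
#' Maps ICD-9 (3-digit roots, subcodes truncated) and ICD-10 (letter plus
#' two digits) underlying-cause codes to the six [CAUSE_CLASSES]:
#' breast cancer is 174 (ICD-9) / C50 (ICD-10); incomplete cancer
#' diagnosis is 195-199 / C76-C80 and C97; the ill-defined chapter is
#' 780-799 / R00-R99; external causes are ICD-9 E-codes and 800-999
#' nature-of-injury codes, and ICD-10 chapters S, T, V-Y; the remaining
#' malignant-neoplasm ranges (140-208 / C00-C97, D00-D48) are "other
#' defined cancer" and everything else "other defined natural".
#'
#' @param icd_code character vector of codes (subcodes such as "C50.9" or
#'   "1749" are truncated to their 3-character root).
#' @param icd_revision 9 or 10, recycled along `icd_code`.
#' @return character vector of class labels (levels of [CAUSE_CLASSES]).
#' @examples
#' classify_cause(c("C50", "C79", "R98"), 10)
#' classify_cause(c("174", "197", "785"), 9)
#' @export
classify_cause <- function(icd_code, icd_revision) {
  code <- toupper(trimws(as.character(icd_code)))
  rev <- as.integer(rep_len(icd_revision, length(code)))
  if (any(!rev %in% c(9L, 10L)))
    stop("icd_revision must be 9 or 10")
  code <- gsub("\\.", "", code)
  out <- character(length(code))

  is9 <- rev == 9L
  if (any(is9)) {
    c9 <- code[is9]
    ecode <- grepl("^E[0-9]{3}", c9)
    num_ok <- grepl("^[0-9]{3}", c9)
    bad <- !ecode & !num_ok
    if (any(bad))
      stop("unparseable ICD-9 code(s): ",
           paste(unique(c9[bad]), collapse = ", "))
    root <- suppressWarnings(as.integer(substr(c9, 1, 3)))
    cls <- rep("OTHER_DEFINED_NATURAL", length(c9))
    cls[!ecode & root >= 140 & root <= 208] <- "OTHER_DEFINED_CANCER"
    cls[!ecode & root == 174] <- "BREAST"
    cls[!ecode & root >= 195 & root <= 199] <- "INCOMPLETE_CANCER"
    cls[!ecode & root >= 780 & root <= 799] <- "ILL_DEFINED"
    cls[ecode | (!is.na(root) & root >= 800 & root <= 999)] <- "NON_NATURAL"
    out[is9] <- cls
  }

  if (any(!is9)) {
    c10 <- code[!is9]
    ok <- grepl("^[A-Z][0-9]{2}", c10)
    if (any(!ok))
      stop("unparseable ICD-10 code(s): ",
           paste(unique(c10[!ok]), collapse = ", "))
    root <- substr(c10, 1, 3)
    letter <- substr(root, 1, 1)
    num <- as.integer(substr(root, 2, 3))
    cls <- rep("OTHER_DEFINED_NATURAL", length(c10))
    cls[letter == "C" | (letter == "D" & num <= 48)] <- "OTHER_DEFINED_CANCER"
    cls[root == "C50"] <- "BREAST"
    cls[root %in% ICD10_INCOMPLETE] <- "INCOMPLETE_CANCER"
    cls[letter == "R"] <- "ILL_DEFINED"
    cls[letter %in% c("S", "T", "V", "W", "X", "Y")] <- "NON_NATURAL"
    out[!is9] <- cls
  }
  out
}
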