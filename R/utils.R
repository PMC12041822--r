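#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# round-half-up (commercial rounding); base round() rounds half to even,
# which would turn e.g. a share of 0.25 into 0.2 rather than 0.3
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# minimal XML text/attribute escaping for the writer; the reader is xml2
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# stable hash of an R object (used for config/corpus provenance in manifests)
object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(tmp))
}

file_hashes <- function(paths) {
  h <- tools::md5sum(paths)
  tibble(file = basename(paths), md5 = unname(h))
}

# elementwise isTRUE: NA and FALSE -> FALSE
isTRUE_vec <- function(x) !is.na(x) & x

icd10_pattern <- "^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$"
obds_gender_codes <- c("M", "W", "D", "U")

fhir_gender_map <- c(M = "male", W = "female", D = "other", U = "unknown")
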