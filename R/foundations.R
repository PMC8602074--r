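#' The five moral foundations
#'
#' Returns the five moral foundations in the fixed order used by every
#' vector-valued quantity in this package: Care, Fairness, Ingroup,
#' Authority, Purity. All loading vectors, profile vectors and homophily
#' tables are indexed in this order.
#'
#' @return A character vector of length five:
#'   `c("CARE", "FAIRNESS", "INGROUP", "AUTHORITY", "PURITY")`.
#' @export
#' @examples
#' moral_foundations()
moral_foundations <- function() {
  c("CARE", "FAIRNESS", "INGROUP", "AUTHORITY", "PURITY")
}

# Sentinel label for users that fail the labeling rules (tied argmax or
# fewer than two moral tweets).
EXCLUDED <- "EXCLUDED"

# Category names map onto foundations by case-insensitive substring so the
# English and Japanese dictionaries (which share the category structure)
# parse through one code path.
foundation_from_category_name <- function(name) {
  n <- tolower(name)
  if (grepl("harm", n) || grepl("care", n)) return("CARE")
  if (grepl("fairness", n)) return("FAIRNESS")
  if (grepl("ingroup", n)) return("INGROUP")
  if (grepl("authority", n)) return("AUTHORITY")
  if (grepl("purity", n)) return("PURITY")
  "GENERAL"
}

polarity_from_category_name <- function(name) {
  n <- tolower(name)
  if (grepl("virtue", n)) return("VIRTUE")
  if (grepl("vice", n)) return("VICE")
  "NONE"
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. A NULL seed leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed from a master seed, kept within the 32-bit
# integer range, so each generator stage has its own independent stream.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587) + 1L
}
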