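# Internal helpers: error classes, seeded evaluation, intensity coding.

MINUTES_PER_DAY <- 1440L
DAY_START_MINUTE <- 180L  # social day starts at 03:00

actema_error <- function(message, class) {
  stop(structure(
    class = c(class, "actema_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

schema_error <- function(message) actema_error(message, "actema_schema_error")
validation_error <- function(message) actema_error(message, "actema_validation_error")
contract_error <- function(message) actema_error(message, "actema_contract_error")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# stream.  seed = NULL evaluates in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

INTENSITY_LEVELS <- c(sedentary = 0L, light = 1L, moderate = 2L, vigorous = 3L)

# Accept c("moderate","vigorous"), integer codes, or a single "+"-joined
# label; return sorted integer codes (sedentary never counts as active).
normalize_intensity_set <- function(set) {
  if (is.numeric(set)) {
    codes <- as.integer(set)
  } else {
    set <- unlist(strsplit(as.character(set), "+", fixed = TRUE))
    unknown <- setdiff(set, names(INTENSITY_LEVELS))
    if (length(unknown)) {
      contract_error(sprintf("unknown intensity level(s): %s",
                             paste(unknown, collapse = ", ")))
    }
    codes <- unname(INTENSITY_LEVELS[set])
  }
  codes <- sort(unique(codes))
  if (length(codes) == 0L || any(!codes %in% 1:3)) {
    contract_error("intensity_set must be a non-empty subset of {light, moderate, vigorous}")
  }
  codes
}

intensity_set_label <- function(set) {
  codes <- normalize_intensity_set(set)
  paste(names(INTENSITY_LEVELS)[match(codes, INTENSITY_LEVELS)], collapse = "+")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

as_date_utc <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}
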