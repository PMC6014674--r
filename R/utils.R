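# Internal helpers shared across modules.

# ODM hierarchy levels, top to bottom (clinical levels below the study).
ODM_LEVELS <- c("study_event", "form", "item_group", "item")

# ODM value data types the statistics engine supports (Table-driven mapping
# onto the Stevens scale categories lives in categorize()).
SUPPORTED_DATA_TYPES <- c("boolean", "string", "text",
                          "integer", "float", "double",
                          "date", "time", "datetime")

# Data type names that are lexically valid ODM but not analyzable here
# (partial/incomplete timepoints, binary blobs, durations, URIs).
KNOWN_UNSUPPORTED_TYPES <- c(
  "partialDate", "partialTime", "partialDatetime",
  "incompleteDate", "incompleteTime", "incompleteDatetime",
  "durationDatetime", "intervalDatetime",
  "hexBinary", "base64Binary", "hexFloat", "base64Float", "URI"
)

is_oid <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}

path_key <- function(path) paste(path, collapse = "/")

`%||%` <- function(a, b) if (is.null(a)) b else a

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream (the fixture generator's determinism contract).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_structural <- function(message, xml_path = "", line = NA_integer_) {
  cond <- structure(
    class = c("odm_structural_error", "error", "condition"),
    list(message = message, call = sys.call(-1),
         xml_path = xml_path, line = line)
  )
  stop(cond)
}
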