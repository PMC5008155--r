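`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage substream seed: mixes a base seed with a stage label
# so that independent pipeline stages never share an RNG stream. Kept within
# the 32-bit signed integer range R requires of set.seed().
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Delimited reader: auto-sniffs comma/tab, strips a UTF-8 BOM, empty = NA.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, na.strings = c("", "NA"), data.table = FALSE,
                           colClasses = NULL, showProgress = FALSE)
  names(tab) <- sub("^﻿", "", names(tab))
  tab
}

# Rename source headers to canonical names using a map
# list(canonical = "source_header", ...); identity when map is NULL.
apply_column_map <- function(tab, map) {
  if (is.null(map) || !length(map)) return(tab)
  for (canon in names(map)) {
    src <- map[[canon]]
    if (!src %in% names(tab))
      stop("column-map source header not found: ", src)
    names(tab)[names(tab) == src] <- canon
  }
  tab
}

# internal assert with a uniform error style
need_cols <- function(tab, cols, what) {
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}
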