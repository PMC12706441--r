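`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-up rounding (round() in R rounds half to even); small epsilon guards
# against values like 45.4999999 that are 45.5 in exact arithmetic.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# Parse ISO-8601-ish timestamps as UTC. Accepts "T" or " " separators and
# bare dates; anything else becomes NA.
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  }
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  ok <- !is.na(x) & nzchar(x)
  fmts <- c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
            "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")
  for (f in fmts) {
    todo <- ok & is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(x[todo], tz = "UTC", format = f)
  }
  out
}

format_utc <- function(t) {
  out <- rep(NA_character_, length(t))
  ok <- !is.na(t)
  out[ok] <- format(t[ok], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out
}

# Identifier normalization used for duplicate matching: lowercase, drop all
# whitespace. Missing or empty values never match anything.
normalize_key <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[[:space:]]+", "", x)
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  x
}

# Minimal union-find over 1..n, used to merge duplicate groups that share
# any one of several identifier keys.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}
uf_roots <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

tokenize_words <- function(x) {
  x <- tolower(as.character(x))
  toks <- strsplit(x, "[^a-z']+")[[1]]
  toks[nzchar(toks)]
}

# Run RNG-dependent code under a fixed seed without disturbing the caller's
# random stream (the simulate() convention).
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
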