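# internal helpers shared across modules

# integer codes for bases; anything outside A/C/G/T (incl. N) codes as 4 and
# never forms a match column
.dna_code_map <- c(A = 0L, C = 1L, G = 2L, T = 3L)

dna_codes <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) stop("`seq` must be a single string")
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  codes <- .dna_code_map[v]
  codes[is.na(codes)] <- 4L
  unname(codes)
}

# round half away from zero (R's round() is half-even); x >= 0 throughout
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# evaluate `code` under a temporary RNG state seeded with `seed`;
# seed = NULL uses (and advances) the current RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single number or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

`%||%` <- function(a, b) if (is.null(a)) b else a
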