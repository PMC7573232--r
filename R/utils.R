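# Internal helpers shared across modules.

# Gene identifiers are matched across datasets by exact string comparison
# after uppercasing and stripping surrounding whitespace, so that e.g. mouse
# "Tcf7" and human "TCF7" meet on the same key when no explicit mapping
# table is supplied.
norm_gene_ids <- function(ids) toupper(trimws(ids))

# Progress/filter logging. Quiet by default so programmatic use stays clean;
# the analysis drivers switch it on with options(nohelpscore.verbose = TRUE).
nhs_log <- function(fmt, ...) {
  if (isTRUE(getOption("nohelpscore.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Run a block with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic half-up rounding (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

geometric_mean <- function(x) exp(mean(log(x)))
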