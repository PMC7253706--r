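# Internal helpers shared across the pipeline.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage-specific seed from a master seed
#'
#' Each pipeline stage draws its randomness from a seed derived
#' deterministically from the master seed and the stage name, so stages can be
#' rerun in isolation with identical randomness. The derivation is an FNV-1a
#' hash of the stage name folded into the master seed, reduced modulo 2^31-1.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name (e.g. `"synthesis"`, `"fold_07"`).
#' @return A positive integer seed strictly below 2^31.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(stage)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  as.integer((abs(master_seed) %% 2147483647 + h * 31) %% 2147483646 + 1)
}

# FNV-1a hash of a character scalar, as 8 hex digits; used to fingerprint
# configurations in reports.
fnv1a_hex <- function(s) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Fingerprint a configuration object
#'
#' Serialises the object to canonical JSON and hashes it, so every output file
#' can record which configuration produced it.
#'
#' @param config Any JSON-serialisable list.
#' @return An 8-hex-digit character hash.
#' @export
config_hash <- function(config) {
  fnv1a_hex(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
}

# Linearised voxel index (1-based) from integer coordinates, and back.
vox_to_index <- function(ijk, dims) {
  ijk[, 1L] + dims[1L] * (ijk[, 2L] - 1L) + dims[1L] * dims[2L] * (ijk[, 3L] - 1L)
}

index_to_vox <- function(idx, dims) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1L]
  j <- (idx0 %/% dims[1L]) %% dims[2L]
  k <- idx0 %/% (dims[1L] * dims[2L])
  cbind(i + 1L, j + 1L, k + 1L)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
  invisible(x)
}
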