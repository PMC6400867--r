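`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("compstress_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("compstress_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_prob <- function(p, what) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_config(what, " must be a probability in [0, 1]")
  invisible(p)
}

#' Stable hash of an R object
#'
#' 32-bit FNV-1a over the canonical serialization of `x`, returned as an
#' 8-character hex string. Used to stamp pipeline artifacts with their
#' generating configuration; not cryptographic.
#'
#' @param x Any serializable R object.
#' @return A character scalar of 8 hex digits.
#' @export
config_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2)
  # skip the serialization header (R version specific)
  bytes <- bytes[-seq_len(14)]
  h <- 2166136261
  for (b in as.integer(bytes)) {
    # xor only touches the low byte (b < 256); keeps h a plain double
    low <- h %% 256
    h <- (h - low) + bitwXor(as.integer(low), b)
    # multiply by the FNV prime 16777619 mod 2^32, exactly, in doubles:
    # split h into 16-bit halves so every product stays below 2^53
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- as.integer(h %% 65536)
  hi <- as.integer((h - lo) / 65536)
  sprintf("%04x%04x", hi, lo)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

# half-Cauchy(0, scale) log density on x > 0
dhalfcauchy_log <- function(x, scale) {
  ifelse(x > 0,
         log(2) - log(pi * scale) - log1p((x / scale)^2),
         -Inf)
}
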