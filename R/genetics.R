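# Genetic-effect integration: effect-coefficient tables, per-agent
# expression profiles, and the tanh link feeding into the kill kernel.

#' Load a gene/pathway effect-coefficient table
#'
#' Reads a CSV/TSV with columns `feature_id`, `beta` and an optional
#' `is_exhaustion_marker` flag. Coefficients are used exactly as
#' supplied; any sign convention (such as negating regression
#' coefficients so that positive beta means pro-cytotoxic) is the data
#' producer's responsibility.
#'
#' @param path File path; the delimiter is sniffed from the extension
#'   (`.tsv` means tab, anything else comma).
#' @return A `gene_effect_table` data frame with columns `feature_id`
#'   (character), `beta` (numeric), `is_exhaustion_marker` (logical).
#' @export
load_effect_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  as_effect_table(raw)
}

#' Validate a data frame as a gene-effect table
#'
#' @param df Data frame with columns `feature_id`, `beta`, optionally
#'   `is_exhaustion_marker`.
#' @return A validated `gene_effect_table`.
#' @export
as_effect_table <- function(df) {
  need <- c("feature_id", "beta")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("effect table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$feature_id)) {
    dup <- df$feature_id[duplicated(df$feature_id)][1]
    stop("duplicate feature_id in effect table: ", dup)
  }
  beta <- suppressWarnings(as.numeric(df$beta))
  if (anyNA(beta)) {
    bad <- df$feature_id[which(is.na(beta))[1]]
    stop("non-numeric beta for feature: ", bad)
  }
  if (any(!is.finite(beta))) stop("non-finite beta in effect table")
  marker <- if ("is_exhaustion_marker" %in% names(df))
    as.logical(df$is_exhaustion_marker) else rep(FALSE, nrow(df))
  marker[is.na(marker)] <- FALSE
  out <- data.frame(feature_id = as.character(df$feature_id), beta = beta,
                    is_exhaustion_marker = marker, stringsAsFactors = FALSE)
  class(out) <- c("gene_effect_table", "data.frame")
  out
}

#' Assign expression profiles to NK agents
#'
#' Draws `n` single-cell profiles uniformly with replacement from the
#' columns of `pool` using the seeded generator, emulating random
#' assignment of pre-infusion single-cell transcriptomes to agents.
#'
#' @param pool Numeric matrix, features x cells; rownames must cover the
#'   effect table's `feature_id`s when used together.
#' @param n Number of profiles to draw.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return An integer vector of length `n` of column indices into
#'   `pool`, with the drawn matrix available via `pool[, idx]`.
#' @export
assign_expression_profiles <- function(pool, n, seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0L) return(integer())
  if (is.null(pool) || ncol(pool) == 0L)
    stop("expression pool is empty but profiles were requested")
  if (!is.null(seed)) set.seed(seed)
  sample.int(ncol(pool), n, replace = TRUE)
}

#' Genetic cytotoxicity effect of one expression profile
#'
#' `G = tanh(b * sum(beta_i * g_i))`: the weighted sum of a profile's
#' expression values over the effect table, squashed into `(-1, 1)` and
#' scaled by the overall coefficient `b`. The result shifts the logistic
#' argument of the kill probability.
#'
#' @param params A [genetic_effect_params()].
#' @param table A `gene_effect_table`.
#' @param profile Numeric vector aligned to `table$feature_id` (or a
#'   named vector / matrix column covering those ids).
#' @return The dimensionless genetic effect, in `(-1, 1)`.
#' @export
genetic_effect <- function(params, table, profile) {
  g <- align_profile(table, profile)
  tanh(params$b * sum(table$beta * g))
}

# Match a profile vector to the effect-table feature order.
align_profile <- function(table, profile) {
  if (!is.null(names(profile))) {
    miss <- setdiff(table$feature_id, names(profile))
    if (length(miss))
      stop("profile missing feature(s): ", paste(miss, collapse = ", "))
    return(as.numeric(profile[table$feature_id]))
  }
  if (length(profile) != nrow(table))
    stop("profile length ", length(profile),
         " does not match effect table of ", nrow(table), " features")
  as.numeric(profile)
}

# Precompute, for a pool of profiles, the pieces of the weighted sum
# that do and do not change under marker accumulation:
#   static  = sum over non-marker features of beta * g
#   markers = matrix (profiles x markers) of initial marker expression
# Per-agent G is then tanh(b * (static + marker_beta %*% x)).
precompute_genetics <- function(table, pool, idx) {
  if (is.null(table) || is.null(pool)) {
    return(list(static = rep(0, length(idx)),
                markers = matrix(0, length(idx), 0),
                marker_beta = numeric(0)))
  }
  rows <- match(table$feature_id, rownames(pool))
  if (anyNA(rows))
    stop("expression pool missing feature(s): ",
         paste(table$feature_id[is.na(rows)], collapse = ", "))
  sub <- pool[rows, idx, drop = FALSE]          # features x agents
  is_m <- table$is_exhaustion_marker
  static <- as.numeric(crossprod(sub[!is_m, , drop = FALSE],
                                 matrix(table$beta[!is_m], ncol = 1)))
  markers <- t(sub[is_m, , drop = FALSE])       # agents x markers
  markers[markers < 0] <- 0
  list(static = static, markers = markers, marker_beta = table$beta[is_m])
}

# Vectorized genetic effect for agent state (static part + current
# marker values under EM2/EM3 feedback).
genetic_effect_vec <- function(b, static, markers, marker_beta) {
  s <- static
  if (length(marker_beta))
    s <- s + as.numeric(markers %*% marker_beta)
  tanh(b * s)
}
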