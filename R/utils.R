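#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic operations in the package
# funnel through this so that a single integer seed makes a whole run
# reproducible without clobbering user RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Split a BIO label into its role ("B", "I", "O") and entity type ("" for O).
label_role <- function(labels) {
  ifelse(labels == "O", "O", substr(labels, 1L, 1L))
}

label_type <- function(labels) {
  ifelse(labels == "O", "", sub("^[BI]-", "", labels))
}

is_bio_label <- function(labels) {
  labels == "O" | grepl("^[BI]-.+$", labels)
}

# Cheap deterministic content hash used for cache keys and run manifests.
# Not cryptographic; collisions only cost a cache miss audit.
content_key <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 17, list.len = 1e6)),
             collapse = "\n")
  sprintf("%08x-%d", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 7919 + 1)) %% 0xFFFFFFFF,
          nchar(s))
}
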