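# Shared fixtures: small deterministic configurations used across test files.

# a lean world: no planted effects, no missingness, small n
null_config <- function(n = 200, seed = 1L, ...) {
  generator_config(n_participants = n, effect_registry = list(),
                   missingness = 0, seed = seed, ...)
}

small_study <- function(n = 200, seed = 1L, ...) {
  generate_study(null_config(n, seed, ...))
}

# partition of an integrated/registration table by one of its columns
partition_of <- function(table, variable, min_cluster_size = 1L) {
  cluster_partition(
    variable,
    stats::setNames(as.character(table[[variable]]), table$sample_code),
    min_cluster_size = min_cluster_size)
}

# independent brute-force rank-biserial: mean of sign(xi - yj) over all pairs
brute_rank_biserial <- function(x, y) {
  s <- outer(x, y, function(a, b) sign(a - b))
  mean(s)
}

# independent permutation generator (iterative heap-style, distinct from the
# package's recursive permutations_of)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
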