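# Shared helpers for the test suite.

# A small grid spec used across tests: 3 fraction levels, 2 e_leak levels
# (4374 points in total, all bursting under the surrogate response because
# every fraction is >= 0.75).
toy_spec <- function() {
  grid_spec(fractions = c(0.75, 1.25, 1.75), e_leak_levels = c(-60, -55))
}

# Even smaller spec for brute-force oracles.
tiny_spec <- function() {
  grid_spec(fractions = c(0.5, 1, 1.5), e_leak_levels = -60)
}

# O(N^2) one-parameter-difference oracle: two instances are family
# neighbours iff they differ in the defining parameter only.  Families are
# the connected components of that relation (which is transitive here, so
# components = equivalence classes of the context columns).
oracle_families <- function(group, defining) {
  defining <- hcofam:::resolve_param(defining)
  others <- setdiff(hco_parameters(), defining)
  n <- nrow(group)
  comp <- seq_len(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        same_ctx <- all(vapply(others, function(p) {
          isTRUE(group[[p]][i] == group[[p]][j])
        }, logical(1)))
        if (same_ctx) comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  split(group[[defining]], comp) |>
    lapply(sort) |>
    unname()
}

# Members of each built family, sorted for comparison with the oracle.
family_member_sets <- function(fams) {
  unname(lapply(fams$members, sort))
}

# Canonicalize a list of numeric vectors for set comparison.
sort_sets <- function(sets) {
  keys <- vapply(sets, function(s) paste(format(s), collapse = ","),
                 character(1))
  sets[order(keys)]
}
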