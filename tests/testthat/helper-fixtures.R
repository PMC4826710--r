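# Shared fixtures: everything is built in code at test time.

aa_profile <- function() cobb_to_profile(aplectus_antarcticus())

aa_params <- function() shape_params_from_profile(aa_profile())

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

tmpfile <- function(name) file.path(tempdir(), name)

# deterministic stream of random slender-body profiles
random_profiles <- function(n, seed = 42L, n_interior = 5L) {
  lapply(seq_len(n), function(i)
    make_fixture("random_monotone", list(n = n_interior), seed = seed + i))
}
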