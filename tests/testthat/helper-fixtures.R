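# Shared fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

# Idealized Form 1 reference and its noise-free restraint set (expensive:
# deterministic assembly + regularization), shared across test files.
form1_reference <- function() {
  if (is.null(.fixtures$ref1)) {
    t1 <- form1_topology()
    ref <- build_idealized_coords(t1)
    peaks <- simulate_noe_peaks(ref, max_distance = 6, noise = noise_model())
    .fixtures$ref1 <- list(topology = t1, ref = ref, peaks = peaks,
                           restraints = qdh_restraints(
                             t1, noe = noe_restraints(peaks)))
  }
  .fixtures$ref1
}

# Minimal duplex-hairpin topology on a 6-mer (three G.C stem pairs): small
# enough for many-structure pipeline runs in seconds.
toy_topology <- function() {
  qdh_topology(
    name = "toy-hairpin", sequence = "GGGCCC",
    pairs = data.frame(g = c(1L, 2L, 3L), c = c(6L, 5L, 4L), role = "stem"),
    loops = list()
  )
}

# A small conformer with a few explicitly placed protons, for NOE
# simulation edge cases.
two_proton_conformer <- function(d) {
  conformer(data.frame(
    resno = c(1L, 1L), resname = "DG", atom = c("H8", "H1'"),
    element = "H", x = c(0, d), y = 0, z = 0, stringsAsFactors = FALSE))
}
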