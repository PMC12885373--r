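# Random interior compositions (caller controls the RNG state).
rcomp <- function(D) composition(rgamma(D, shape = 1, rate = 1) + 1e-8)

# A small 3-taxon tree fixture used across diversity/unifrac tests.
tree3 <- function(seed = 42L) simulate_tree(paste0("taxon_", 1:3), seed)

# ALR -> clr preimage matrix for a contrast basis.
clr_preimage <- function(psi) t(psi) %*% solve(psi %*% t(psi))
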