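# Shared fixtures: maps and strains used across tests.
# The 1 cM eat-5 -- bli-4 distance is a package choice (the loci are known
# to be linked on I; no two-point distance is assumed).

fixture_map <- function() {
  genetic_map(locus("bli-4", "I", 0),
              locus("eat-5", "I", 1),
              locus("sef-1", "II", 5),
              locus("unc-2", "X", 3))
}

# the standard five-marker mapping panel: one visible marker per autosome
# plus the X marker
marker_panel <- function() {
  genetic_map(locus("bli-4", "I", 0), locus("rol-6", "II", 10),
              locus("vab-7", "III", 10), locus("unc-31", "IV", 10),
              locus("dpy-11", "V", 10), locus("lon-2", "X", 5))
}

# binomial Monte Carlo tolerance: k standard errors on a proportion
prop_tol <- function(p, n, k = 4) k * sqrt(p * (1 - p) / n)
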