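#!/usr/bin/env Rscript
# Stage 1 -- build the synthetic study system.
#
# The real study sampled Cichlidogyrus gill parasites from 18 tropheine
# cichlid species; sequence data cannot be bundled here, so the workflow
# runs on a simulated tanglegram with a known event history: a 16-tip host
# tree (the scale of the tropheine radiation), a parasite tree grown on it
# under a cospeciation-dominated event process, binary host-parasite links,
# and an ITS-like alignment evolved along the parasite tree. Everything
# downstream (delimitation, reconciliation, congruence, diversification)
# reads the files written here, and the recorded true event tally lets
# stage 3 be judged against the truth.

suppressMessages(library(cophyr))

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2024L

host <- simulate_yule(16, 1, seed = stage_seed(seed, 0), labels = sprintf("H%02d", 1:16))
host$edge.length <- host$edge.length / max(ape::node.depth.edgelength(host))

params <- sim_params()  # cospeciation-dominated defaults, documented in the vignette
sim <- NULL
s <- 0L
while (is.null(sim)) {
  s <- s + 1L
  sim <- tryCatch(simulate_cophylogeny(host, params, seed = stage_seed(seed, s)),
                  error = function(e) NULL)
}
stopifnot(identical(replay_cophylogeny(sim)$tally, sim$tally))

message(sprintf("simulated %d parasite lineages on %d hosts (attempt %d)",
                ape::Ntip(sim$parasite), ape::Ntip(sim$host), s))
message(sprintf("true events: %d cospeciation, %d sorting, %d duplication, %d host-switch",
                sim$tally[["cospeciation"]], sim$tally[["sorting"]],
                sim$tally[["duplication"]], sim$tally[["switching"]]))

write_newick(sim$host, file.path(out, "host.nwk"))
write_newick(sim$parasite, file.path(out, "parasite.nwk"))
write_links(sim$links, file.path(out, "links.tsv"))

# ITS-like nuclear alignment: ~1400 bp with gamma rate heterogeneity
aln <- simulate_sequences(sim$parasite, 1400, rate = 0.08,
                          seed = stage_seed(seed, 100), gamma_shape = 0.4)
write_alignment(aln, file.path(out, "its.fa"))

# patristic distances for the distance-based congruence stage
write_distance_matrix(patristic_distances(sim$host), file.path(out, "host_distances.tsv"))
write_distance_matrix(patristic_distances(sim$parasite), file.path(out, "parasite_distances.tsv"))

truth <- list(seed = seed, attempt = s, params = unclass(params),
              tally = as.list(sim$tally),
              n_host_tips = ape::Ntip(sim$host),
              n_parasite_tips = ape::Ntip(sim$parasite))
jsonlite::write_json(truth, file.path(out, "truth.json"), auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("wrote ", out)
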