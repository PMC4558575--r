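#!/usr/bin/env Rscript
# Stage 4 -- distance-based congruence test.
#
# Tests the independence of host and parasite patristic distances given the
# links (9999 permutations of host identities, add-one p-value) and reports
# per-link contributions, mirroring the global-plus-links layout of the
# published distance-based analysis.

suppressMessages(library(cophyr))

src <- "results/synthetic"
out <- "results/congruence"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2024L

host_D <- read_distance_matrix(file.path(src, "host_distances.tsv"))
parasite_D <- read_distance_matrix(file.path(src, "parasite_distances.tsv"))
links <- read_links(file.path(src, "links.tsv"))

res <- parafit_links(host_D, parasite_D, links, n_perm = 9999,
                     seed = stage_seed(seed, 401))
n_sig <- sum(res$links$p_value <= 0.05)
message(sprintf("global congruence: statistic %.4g, p = %.4g (%d permutations)",
                res$statistic, res$p_value, res$n_perm))
message(sprintf("%d of %d links individually significant at 0.05", n_sig,
                nrow(res$links)))

utils::write.table(format(res$links, digits = 4), file.path(out, "link_tests.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(statistic = res$statistic, p_value = res$p_value,
                          n_perm = res$n_perm, n_links = nrow(res$links),
                          n_links_significant = n_sig,
                          seed = res$seed),
                     file.path(out, "summary.json"), auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("wrote ", out)
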