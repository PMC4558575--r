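#!/usr/bin/env Rscript
# Stage 3 -- event-based reconciliation with adaptive costs.
#
# Preprocesses the parasite tree the way the real analysis does (collapse
# weakly supported nodes, collapse terminal single-host clades), estimates
# event costs adaptively (costs anti-proportional to inferred event
# frequencies), writes the ranked solution table in the conventional
# quality / total cost / four-counts-with-costs layout, applies the
# plausibility filter that discards degenerate zero-switch solutions,
# checks chronological consistency, compares the inferred tally with the
# simulation truth, and runs the maximum-cospeciation randomization test of
# topological congruence.

suppressMessages(library(cophyr))

src <- "results/synthetic"
out <- "results/reconciliation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2024L

host <- parse_newick(readLines(file.path(src, "host.nwk"))[1])
parasite <- parse_newick(readLines(file.path(src, "parasite.nwk"))[1])
links <- read_links(file.path(src, "links.tsv"))
truth <- jsonlite::read_json(file.path(src, "truth.json"))

coll <- collapse_terminal_host_clades(parasite, links)
message(sprintf("terminal single-host clades: %d -> %d parasite leaves",
                ape::Ntip(parasite), ape::Ntip(coll$tree)))

# adaptive cost estimation (2000 sampled cost sets keep this stage under a
# minute at this problem size; the sampling density, not the search
# principle, is the only thing scaled down)
est <- estimate_costs(host, coll$tree, coll$links, n_sets = 2000,
                      seed = stage_seed(seed, 301),
                      options = reconcile_options(allow_polytomies = TRUE))
utils::write.table(format(est$ranked, digits = 4), file.path(out, "ranked_schemes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# independent (topology-randomization) evidence of congruence, used below as
# the biological context for judging candidate cost schemes
cosp <- cospeciation_significance(host, coll$tree, coll$links, n_rand = 2000,
                                  seed = stage_seed(seed, 302),
                                  options = reconcile_options(allow_polytomies = TRUE))
message(sprintf("max-cospeciation randomization: observed %d, p = %.4g (%d random tree pairs)",
                cosp$observed, cosp$p_value, cosp$n_rand))

# Anti-proportional cost estimation is known to admit degenerate fixpoints
# in which an event type is priced out of use entirely; cost schemes must be
# judged on biological context, not statistics alone. Walk the ranked
# solutions and take the best one that (i) passes the zero-event/extreme-cost
# plausibility filter and (ii) does not deny cospeciation outright when the
# randomization test independently demonstrates topological congruence.
congruent <- cosp$p_value <= 0.05
chosen <- NULL
for (i in seq_len(nrow(est$ranked))) {
  row <- est$ranked[i, ]
  counts <- c(cospeciation = row$cospeciation, sorting = row$sorting,
              duplication = row$duplication, switching = row$switching)
  costs <- c(row$c_cospeciation, row$c_sorting, row$c_duplication, row$c_switching)
  fl <- flag_implausible(counts, costs)
  if (fl$flagged) {
    message(sprintf("rank %d rejected (filter): %s", i, fl$reasons[1]))
    next
  }
  if (congruent && counts[["cospeciation"]] == 0L) {
    message(sprintf("rank %d rejected (context): zero cospeciations despite significant congruence", i))
    next
  }
  chosen <- row
  break
}
stopifnot(!is.null(chosen))
costs <- cost_scheme(chosen$c_cospeciation, chosen$c_sorting,
                     chosen$c_duplication, chosen$c_switching)
rec <- reconcile(host, coll$tree, coll$links, costs,
                 reconcile_options(allow_polytomies = TRUE))
rec$quality <- chosen$quality
tab <- event_table(rec)
message(sprintf("retained scheme: quality %.3g, total cost %.3g", rec$quality,
                tab$total_cost))
message(sprintf("inferred events: %d cospeciation, %d sorting, %d duplication, %d host-switch",
                tab$cospeciation, tab$sorting, tab$duplication, tab$switching))
message(sprintf("true events:     %s cospeciation, %s sorting, %s duplication, %s host-switch",
                truth$tally$cospeciation, truth$tally$sorting,
                truth$tally$duplication, truth$tally$switching))

utils::write.table(format(tab, digits = 4), file.path(out, "event_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

chron <- check_chronology(host, rec)
message("chronological consistency of retained reconciliation: ", chron)

jsonlite::write_json(list(event_table = tab,
                          quality = rec$quality,
                          chronologically_consistent = chron,
                          true_tally = truth$tally,
                          cospeciation_test = cosp[c("observed", "p_value", "n_rand")]),
                     file.path(out, "summary.json"), auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("wrote ", out)
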