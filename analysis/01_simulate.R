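#!/usr/bin/env Rscript
# Stage 1: simulate the study corpus.
#
# Generates 20 synthetic annotated movies (3 genres x release years
# 1940-2010) with embedded sequences and montages, plus 3-viewer boundary
# responses, and writes them under results/corpus/.

suppressMessages(library(cinevents))

seed <- 20260901
out_dir <- file.path("results", "corpus")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

corpus <- generate_corpus(generator_config(n_movies = 20L), seed = seed)
responses <- generate_viewer_responses(corpus, seed = seed + 1L)

for (id in names(corpus$movies))
  write_movie(corpus$movies[[id]], file.path(out_dir, paste0(id, ".json")))
write_responses(responses, file.path(out_dir, "responses.csv"))

truth_classes <- dplyr::bind_rows(lapply(corpus$truth,
                                         function(t) t$boundary_classes))
utils::write.csv(truth_classes, file.path(out_dir, "truth_classes.csv"),
                 row.names = FALSE)

n_shots_tot <- sum(vapply(corpus$movies, n_shots, 1L))
cat(sprintf("simulated %d movies, %d shots, %d boundaries (seed %d)\n",
            length(corpus$movies), n_shots_tot,
            nrow(truth_classes), seed))
cat(sprintf("wrote %s\n", out_dir))
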