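#!/usr/bin/env Rscript
# Populate the local UniProt FASTA cache for the 32 PSY homologs.
# Requires network access once; every other analysis step is offline.
# The cache lands in uniprot_cache/ next to the working directory and is
# found automatically by the downstream scripts (or point them elsewhere
# via options(psykit.cache_dir = ...)).

library(psykit)

res <- fetch_accessions(psy_manifest(), cache_dir = "uniprot_cache")
cat(sprintf("cached %d of %d sequences\n", nrow(res$records),
            nrow(psy_manifest())))
if (nrow(res$failures) > 0L) {
  cat("failed entries:\n")
  print(res$failures)
}
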