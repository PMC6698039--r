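#!/usr/bin/env Rscript
# One-page text report assembled from the saved outputs of scripts 01-04
# (nothing is recomputed). Run after the other analysis scripts.

suppressPackageStartupMessages(library(barriercea))

render_summary("results")
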