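# Shared settings for the numbered analysis drivers. Each script is a thin
# narrative layer over the ucmeth package; all computation lives in R/.
suppressMessages(library(ucmeth))

SEED <- 7
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

say <- function(...) cat(sprintf(...), "\n")
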