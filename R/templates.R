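#' Reconstructed validation-cohort sample sheet
#'
#' A row-level sample sheet rebuilt from the published marginal counts of the
#' 79-patient UC validation cohort: 48/31 male/female; disease duration
#' 41/24/14 (<=1y / 1-8y / >9y); lesion location 44/25/10 (proctitis /
#' left-sided / pancolitis); Mayo endoscopic score 3/23/44/9 (inactive /
#' mild / moderate / severe); clinical type 39/35/5 (one episode / chronic
#' relapsing / chronic continuous). Ages are a synthetic vector constrained
#' to the published mean (42.4 years) and range (16-68); only the marginals
#' are faithful — the joint assignment of categories to patients is
#' arbitrary (fields are filled independently in fixed order).
#'
#' @return sample-sheet data.frame with 79 UC rows.
#' @export
uc_cohort_template <- function() {
  n <- 79L
  fill <- function(counts, labels) rep(labels, counts)
  ages <- c(16L, rep(42L, 45L), rep(43L, 32L), 68L)  # mean 42.405 -> 42.4
  stopifnot(length(ages) == n, abs(mean(ages) - 42.4) < 0.05)
  data.frame(
    sample_id = sprintf("UC%03d", seq_len(n)),
    group = "UC",
    inflammation = NA_character_,
    age = ages,
    sex = fill(c(48, 31), c("male", "female")),
    duration_class = fill(c(41, 24, 14), c("<=1y", "1-8y", ">9y")),
    lesion_location = fill(c(44, 25, 10),
                           c("proctitis", "left_sided", "pancolitis")),
    mayo_class = fill(c(3, 23, 44, 9),
                      c("inactive", "mild", "moderate", "severe")),
    clinical_type = fill(c(39, 35, 5),
                         c("one_episode", "chronic_relapsing",
                           "chronic_continuous")),
    stringsAsFactors = FALSE)
}

#' Reconstructed MSP call table for the three-gene panel
#'
#' Row-level methylation-specific PCR calls for the candidate panel
#' (KIAA1614, RIBC2, FAM217B) rebuilt from the published frequencies: 91\%,
#' 64\% and 62\% methylated among 79 UC samples (realized as 72, 51 and 49
#' methylated calls) and low methylation among the 8 normal-colon controls
#' (realized as 1, 1 and 0).
#'
#' @return MSP data.frame: sample_id, group, gene, call.
#' @export
uc_msp_template <- function() {
  uc_ids <- sprintf("UC%03d", 1:79)
  nc_ids <- sprintf("NC%02d", 1:8)
  gene_counts <- list(KIAA1614 = c(uc = 72L, nc = 1L),
                      RIBC2 = c(uc = 51L, nc = 1L),
                      FAM217B = c(uc = 49L, nc = 0L))
  rows <- lapply(names(gene_counts), function(g) {
    ct <- gene_counts[[g]]
    rbind(
      data.frame(sample_id = uc_ids, group = "UC", gene = g,
                 call = rep(c("methylated", "unmethylated"),
                            c(ct[["uc"]], 79L - ct[["uc"]])),
                 stringsAsFactors = FALSE),
      data.frame(sample_id = nc_ids, group = "NC", gene = g,
                 call = rep(c("methylated", "unmethylated"),
                            c(ct[["nc"]], 8L - ct[["nc"]])),
                 stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
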