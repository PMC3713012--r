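#' Cross-reactivity score table of the 23-peptide Melan-A study set
#'
#' The published activity table used to build the QSAR models: 12
#' cross-reactive decapeptides (scores 56 down to 3, from the 17-clone
#' recognition assay) plus 11 HLA-A2-binding peptides not recognized by
#' any Melan-A-specific clone, all carrying the floor score of -17.
#' These printed scores are model input, not computed output. The ids
#' follow the originating positional-scanning library study.
#'
#' @return named integer vector of length 23 in table order.
#' @export
melanA_activity_table <- function() {
  c(`10` = 15L, `22` = 56L, `23` = 3L, `25` = 39L, `29` = 13L,
    `30` = 16L, `37` = 6L, `56` = 11L, `58` = 3L, `60` = 9L,
    `71` = 15L, `72` = 12L,
    `100` = -17L, `101` = -17L, `102` = -17L, `103` = -17L,
    `104` = -17L, `105` = -17L, `106` = -17L, `107` = -17L,
    `108` = -17L, `109` = -17L, `110` = -17L)
}

#' Peptide sequences of the Melan-A study set
#' @return named character vector (one-letter sequences) matching
#'   [melanA_activity_table()].
#' @export
melanA_sequences <- function() {
  c(`10` = "LLAGIGTVPI", `22` = "EAAGIGILTV", `23` = "RQAGIAGHTY",
    `25` = "VIAGIGILAI", `29` = "NTTDIGIHVV", `30` = "MIAGIGISLI",
    `37` = "RITGICFHFG", `56` = "MLSGIGIFFI", `58` = "VLSSIGIFPI",
    `60` = "RVTGIGLLTG", `71` = "RSAFIGIDPA", `72` = "LLAGIAIGPW",
    `100` = "FLPSDFFPSV", `101` = "KLVALGINAV", `102` = "LLFNILGGWV",
    `103` = "GLYDGMEHTV", `104` = "VLYRYGSFSV", `105` = "TLVEVTLGEV",
    `106` = "LLKYRAREPV", `107` = "ALVETSYVKV", `108` = "VLPDVFIRCV",
    `109` = "LLFGLALIEV", `110` = "ALSRKVAELV")
}

#' Published inactive test-set choice of the Melan-A study
#'
#' The three non-cross-reactive peptides placed in the external test set
#' (the tied -17 block offers no ranking, so the published choice is a
#' recorded random draw).
#'
#' @return character vector of peptide ids.
#' @export
melanA_test_inactives <- function() c("100", "104", "108")

#' Relative functional avidity of the ELS and ELT analogs
#'
#' Per-clone means of log10(EC50_reference / EC50_analog) for the two
#' position-3 analogs of the anchor-optimized Melan-A peptide, measured
#' on six Melan-A-specific CTL clones. These printed values are input
#' data for the avidity arithmetic.
#'
#' @return numeric matrix, rows ELS/ELT, columns the six clones.
#' @export
elx_avidity_table <- function() {
  m <- rbind(
    ELS = c(-0.59, -0.41, -0.07, -0.01, -0.99, -2.44),
    ELT = c(-0.19, -2.17, 0.09, -0.05, -1.88, -1.59))
  colnames(m) <- c("203-R7", "25-R3", "203-R2", "203-R1", "203-R3", "25-R35")
  m
}
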