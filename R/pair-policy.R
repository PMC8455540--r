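#' Combine mate verdicts into pair routing decisions
#'
#' Cleaned R1 and R2 files must stay in lockstep, so a pair is written to the
#' paired outputs only when both mates pass. When exactly one mate passes,
#' the survivor is either dropped with its partner (the default, which keeps
#' the paired outputs aligner-ready) or, with `keep_orphans`, written to a
#' separate unpaired file.
#'
#' @param v1,v2 Verdicts for the R1 and R2 mates: either the tibbles
#'   returned by [evaluate_reads()] or plain `"pass"`/`"fail"` character
#'   vectors.
#' @param keep_orphans Route single survivors to unpaired output instead of
#'   dropping them?
#' @return Character vector of routings: `"both_pass"`, `"both_drop"`,
#'   `"orphan_r1"` or `"orphan_r2"`.
#' @export
resolve_pair <- function(v1, v2, keep_orphans = FALSE) {
  s1 <- if (is.data.frame(v1)) v1$status else v1
  s2 <- if (is.data.frame(v2)) v2$status else v2
  if (length(s1) != length(s2)) {
    abort("mate verdict vectors must have equal length")
  }
  p1 <- s1 == "pass"
  p2 <- s2 == "pass"
  dplyr::case_when(
    p1 & p2 ~ "both_pass",
    p1 & !p2 & keep_orphans ~ "orphan_r1",
    !p1 & p2 & keep_orphans ~ "orphan_r2",
    .default = "both_drop"
  )
}
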