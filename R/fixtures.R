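#' Normalized gamete frequencies for four dominant triples of the classic
#' mouse F2 panel
#'
#' ELS-estimated, normalized sister-pair gamete frequencies for the four
#' linked triples among dominant-converted markers 1, 2, 3 and 5 of the
#' widely distributed 333-individual mouse F2 RFLP panel (the example data
#' shipped with MAPMAKER/EXP 3.0b).  Columns follow the package's class
#' conventions: `p1` = f(abc), `p2` = f(Abc) (class 100), `p3` = f(abC)
#' (class 001), `p4` = f(aBc) (class 010).  The raw genotype data are not
#' redistributed; these per-triple summaries support worked examples and
#' regression checks of the downstream order/phase/recombination pipeline.
#'
#' @return Data frame with columns `a`, `b`, `c`, `p1`..`p4`.
#' @export
mouse_dominant_triples <- function() {
  data.frame(
    a = c("1", "1", "1", "2"),
    b = c("2", "2", "3", "3"),
    c = c("3", "5", "5", "5"),
    p1 = c(0.208668, 0.200976, 0.209093, 0.202566),
    p2 = c(0.086162, 0.080676, 0.065783, 0.085775),
    p3 = c(0.094698, 0.108494, 0.122370, 0.112098),
    p4 = c(0.110472, 0.109854, 0.102753, 0.099561),
    stringsAsFactors = FALSE)
}
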