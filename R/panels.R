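#' Standard pharmacogene panels
#'
#' The nested minimum gene panels: the 3-gene base panel (`CYP2C19`,
#' `CYP2C9`, `CYP2D6`); the 5-gene panel adding `CYP3A4` and `CYP3A5`; the
#' 14-gene panel adding `CYP2B6`, `CYP4F2`, `SLCO1B1`, `TPMT`, `DPYD`,
#' `HLA-B*57:01`, `IFNL3`, `UGT1A1`, `VKORC1`; and the 25-gene panel adding
#' `ADRA2A`, `COMT`, `CYP1A2`, `F2`, `F5`, `GRIK4`, `HTR2A`, `HTR2C`,
#' `MTHFR`, `NAT2`, `OPRM1`. Each panel is a superset of the smaller ones.
#'
#' @param size one of 3, 5, 14, 25.
#' @return character vector of gene symbols.
#' @export
#' @examples
#' pgx_panel(5)
pgx_panel <- function(size) {
  p3 <- c("CYP2C19", "CYP2C9", "CYP2D6")
  p5 <- c(p3, "CYP3A4", "CYP3A5")
  p14 <- c(p5, "CYP2B6", "CYP4F2", "SLCO1B1", "TPMT", "DPYD", "HLA-B*57:01",
           "IFNL3", "UGT1A1", "VKORC1")
  p25 <- c(p14, "ADRA2A", "COMT", "CYP1A2", "F2", "F5", "GRIK4", "HTR2A",
           "HTR2C", "MTHFR", "NAT2", "OPRM1")
  switch(as.character(size), `3` = p3, `5` = p5, `14` = p14, `25` = p25,
         stopf("panel size must be one of 3, 5, 14, 25"))
}
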