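#' Conserved plant-mitochondrial protein-coding gene table
#'
#' The 36 conserved protein-coding genes of an upland-cotton-style
#' mitogenome, with the coding length (bp, stop codon included), intron
#' count and start codon used by the synthetic generator. The documented
#' anchors of the set are: eight intron-bearing genes (nad1, nad2, nad5 and
#' nad7 with four introns each; cox2, ccmFC, rps3 and rps10 with one each),
#' coding lengths spanning 303 bp (nad4L) to 2013 bp (nad5), ACG starts for
#' nad1, nad4L and rps10, an ATT start for mttB, and ATG elsewhere. The
#' remaining lengths are plausible in-range values for the respective gene
#' families, not measured ones.
#'
#' @return A data frame: `name`, `cds_len`, `introns`, `start_codon`,
#'   `copies`.
#' @export
conserved_gene_table <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name    cds_len introns start_codon
nad1    978     4       ACG
nad2    1467    4       ATG
nad3    357     0       ATG
nad4    1488    0       ATG
nad4L   303     0       ACG
nad5    2013    4       ATG
nad6    720     0       ATG
nad7    1185    4       ATG
nad9    573     0       ATG
cox1    1584    0       ATG
cox2    783     1       ATG
cox3    798     0       ATG
cob     1182    0       ATG
atp1    1530    0       ATG
atp4    597     0       ATG
atp6    723     0       ATG
atp8    480     0       ATG
atp9    312     0       ATG
ccmB    621     0       ATG
ccmC    753     0       ATG
ccmFC   1341    1       ATG
ccmFN   1743    0       ATG
matR    1968    0       ATG
mttB    834     0       ATT
rps3    1680    1       ATG
rps4    1068    0       ATG
rps7    447     0       ATG
rps10   357     1       ACG
rps12   378     0       ATG
rps14   306     0       ATG
rps19   309     0       ATG
rpl2    999     0       ATG
rpl5    555     0       ATG
rpl10   480     0       ATG
rpl16   543     0       ATG
sdh4    420     0       ATG
")
  df$copies <- 1L
  df
}
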