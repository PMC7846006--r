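# Packaged data files

All files are small plain-text transcriptions or synthetic stand-ins; the
loader (`load_fixture()`) verifies the TSVs against `fixture_checksums.tsv`.

* `table2_total_snps.tsv` — total SNP counts (all categories combined) per
  subject and tissue.
* `table3_homoplasmy.tsv` — germline homoplasmy SNPs with per-sample printed
  percentage frequencies. Five rows carry a `note` instead of Subject-2
  values: at those positions the reference sequence itself carries the
  non-H allele, so the H-lineage subject shows no SNP.
* `table5_heteroplasmy.tsv` — heteroplasmy SNPs with per-sample printed
  percentage frequencies. Transcribed verbatim, including two documented
  internal inconsistencies of the printed source: the row list contains
  167 Subject-3 blood entries although the printed per-tissue totals say
  165, and Subject-2 blood contains the transversion 6266A>C (1.47%)
  although the printed transversion summary lists only 6 Subject-2
  transversions.
* `table7_annotations.tsv` — hot-spot SNP annotations (locus, amino-acid
  change, rs number, pathogenicity notes), as printed.
* `table8_cohort.tsv` — hot-spot carrier counts in the 222-subject blood
  cohort (Young-NL n=83, Old-NL n=66, Old-AMD n=73), as printed.
* `mini_haplotree.tsv` — simplified haplogroup tree whose root-to-leaf
  paths carry the three subjects' homoplasmy sets as defining SNPs, plus
  decoy branches (H1, J, K). 263A>G appears on both the H and U branches
  (deliberate homoplasy: the I-lineage subject lacks it while the H- and
  U-lineage subjects carry it).
* `mt_reference_synthetic.fasta` — synthetic 16,569-bp circular reference:
  rCRS length, with the documented reference base at every position any
  fixture uses and seeded pseudo-random bases elsewhere. It is *not* the
  rCRS sequence; supply a real rCRS FASTA to `load_reference()` for real
  data.
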