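# Published clinicopathological counts for the two cutaneous melanoma
# cohorts (BCH discovery, TCGA replication) and the acral cohort, as
# printed in the cohort characteristics table. Used for the contingency
# statistics that the pipeline reproduces.
tumor_type:
  description: primary vs metastatic, cutaneous BCH vs cutaneous TCGA
  columns: [primary, metastatic]
  rows:
    - label: cutaneous_bch
      counts: [20, 34]
    - label: cutaneous_tcga
      counts: [9, 49]
molecular_group:
  description: BRAF/RAS/NF1/TN molecular groups, cutaneous BCH vs TCGA
  columns: [bch, tcga]
  rows:
    - label: BRAF
      counts: [39, 23]
    - label: RAS
      counts: [6, 20]
    - label: NF1
      counts: [2, 6]
    - label: TN
      counts: [7, 9]
uv_signature:
  description: UV-signature yes/no, cutaneous BCH vs acral BCH
  columns: [uv_yes, uv_no]
  rows:
    - label: cutaneous_bch
      counts: [44, 10]
    - label: acral_bch
      counts: [4, 17]
uv_signature_tcga:
  description: UV-signature yes/no in cutaneous TCGA (annotation only)
  columns: [uv_yes, uv_no]
  rows:
    - label: cutaneous_tcga
      counts: [47, 11]
skin_phenotype:
  description: white vs pigmented skin, cutaneous BCH vs acral BCH
  columns: [white, pigmented]
  rows:
    - label: cutaneous_bch
      counts: [51, 3]
    - label: acral_bch
      counts: [15, 6]
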