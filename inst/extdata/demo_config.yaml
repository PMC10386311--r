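# Demonstration cohort: eight individuals across a sea-level site (PO01)
# and two altitude sites (PO12, PO16), rDNA copy numbers spanning the
# 300-1200 range, mixed ETS genotypes and a few rRNA-gene SNPs.
seed: 1
depth: 3
read_len: 150
insert_mean: 350
insert_sd: 35
error_rate: 0.001
dup_rate: 0.02
backbone_length: 100000
genotype_mode: truth
grouping:
  PO01: sea
  PO12: altitude
  PO16: altitude
individuals:
  - id: PO01A
    copy_number: 650
    altitude: 2
    mixture:
      - {ets5: VARA, ets3: VAR1, prop: 0.8}
      - {ets5: VARB, ets3: VAR1, prop: 0.2}
  - id: PO01B
    copy_number: 300
    altitude: 2
    mixture:
      - {ets5: VARA, ets3: VAR1, prop: 0.55}
      - {ets5: VARB, ets3: VAR2, prop: 0.25}
      - ets5: VARB
        ets3: VAR2
        prop: 0.2
        snps:
          - {pos: 4100, alt: A}
  - id: PO01C
    copy_number: 520
    altitude: 2
    mixture:
      - {ets5: VARA, ets3: VAR1, prop: 0.45}
      - {ets5: VARB, ets3: VAR2, prop: 0.45}
      - {ets5: VARA, ets3: VAR4, prop: 0.1}
  - id: PO12A
    copy_number: 840
    altitude: 1000
    mixture:
      - {ets5: VARA, ets3: VAR1, prop: 0.75}
      - {ets5: VARB, ets3: VAR3, prop: 0.25}
  - id: PO12B
    copy_number: 460
    altitude: 1000
    mixture:
      - {ets5: VARA, ets3: VAR1, prop: 0.8}
      - ets5: VARB
        ets3: VAR1
        prop: 0.2
        snps:
          - {pos: 2210, alt: C}
  - id: PO16A
    copy_number: 1200
    altitude: 1500
    mixture:
      - {ets5: VARA, ets3: VAR1, prop: 0.8}
      - {ets5: VARB, ets3: VAR1, prop: 0.2}
  - id: PO16B
    copy_number: 700
    altitude: 1500
    mixture:
      - {ets5: VARA, ets3: VAR1, prop: 0.375}
      - {ets5: VARA, ets3: VAR3, prop: 0.375}
      - {ets5: VARB, ets3: VAR7, prop: 0.25}
  - id: PO16C
    copy_number: 580
    altitude: 1500
    mixture:
      - {ets5: VARA, ets3: VAR1, prop: 0.5}
      - {ets5: VARB, ets3: VAR1, prop: 0.5}
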