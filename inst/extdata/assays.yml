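# Published MethyLight assay definitions, oligo sequences exactly as
# printed (uppercase marks CpG-derived discriminating bases).
#
# Note on orientation: the printed COL2A1 "forward" primer is C-rich and
# G-free, so it anneals to the complement of the converted template (it
# functions as the reverse primer of the converted strand); the printed
# probe of the 70-bp assay likewise sits on the opposite product strand.
# locate_oligo() handles probes with orientation "auto"; the COL2A1 assay is
# methylation-neutral and is never placed on a template by the toolkit.
assays:
  - name: ML-70bp-classic
    target_strand: antisense
    reference: false
    amplicon_tss: [238, 307]
    nominal_length: 70
    forward:
      name: ML-Primer-F1
      sequence: "tggag ttttC ggttg attgg tt"
    reverse:
      name: ML-Primer-R1
      sequence: "aacaa cGccc Gcacc tcct"
    probe:
      name: ML-Probe-1
      sequence: "accCg acccC gaacC gCg"
      label: "6FAM/TAMRA"
  - name: ML-115bp-novel
    target_strand: sense
    reference: false
    amplicon_tss: [157, 272]
    nominal_length: 115
    forward:
      name: ML-Primer-F2
      sequence: "CgCgg tCgtg gttag ttagt"
    reverse:
      name: ML-Primer-R2
      sequence: "tacGc tcGac Gacta Cgaaa"
    probe:
      name: ML-Probe-2
      sequence: "gttgt ttttC gtCgt Cggtt"
      label: "6FAM/TAMRA"
  - name: COL2A1-reference
    target_strand: sense
    reference: true
    forward:
      name: COL2A1-F
      sequence: "tctaa caatt ataaa ctcca accac caa"
    reverse:
      name: COL2A1-R
      sequence: "gggaa gatgg gatag aaggg aatat"
    probe:
      name: COL2A1-Probe
      sequence: "ccttc attct aaccc aatac ctatc ccacc tctaa a"
      label: "6FAM/BHQ1"
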