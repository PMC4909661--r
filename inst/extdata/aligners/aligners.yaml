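# Aligner command templates. Placeholders: {input} {output} {gop} {gep}
# {matrix_flag}. A ">" token means the tool writes the alignment to stdout,
# which the runner captures to {output} (no shell is involved).
builtin:
  is_builtin: true

# MAFFT, L-INS-i-style strategy. Caveats, both documented in the package
# vignette: MAFFT's --ep is a score offset whose semantics differ subtly
# from a textbook gap-extension penalty (values are passed verbatim), and
# MAFFT exposes no Dayhoff PAM tables, so PAM100/PAM200 map to the JTT-PAM
# variants --jtt 100/200 here. Edit the template to change strategy.
mafft-linsi:
  command_template: "mafft --localpair --maxiterate 1000 --op {gop} --ep {gep} {matrix_flag} --quiet {input} > {output}"
  matrix_flag_map:
    BLOSUM30: "--bl 30"
    BLOSUM45: "--bl 45"
    BLOSUM62: "--bl 62"
    BLOSUM80: "--bl 80"
    PAM100: "--jtt 100"
    PAM200: "--jtt 200"
  timeout_s: 600

# CLUSTALW default matrix series (no per-matrix flag mapping).
clustalw:
  command_template: "clustalw -INFILE={input} -OUTFILE={output} -OUTPUT=FASTA -GAPOPEN={gop} -GAPEXT={gep} -ALIGN -QUIET"
  timeout_s: 600
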