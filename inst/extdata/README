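Optional data
=============

cosmic_v2_signatures.tsv
    The COSMIC Ver. 2 single-base-substitution signature probability
    matrix (30 signatures x 96 trinucleotide channels), available from the
    COSMIC signatures website as "signatures_probabilities.txt".  It is not
    redistributed with this package.  Placing it here (any orientation
    accepted by read_signature_matrix()) enables the signature-catalog
    analytic checks in the acceptance suite and the corresponding entries
    of scripts/acceptance.R.
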