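# Consequence-term impact vocabulary.
# Terms expected to disrupt protein function are "impactful"; terms expected
# to leave the protein unchanged are "non_impactful". Samples whose only
# variants are non-impactful form the excluded group, later re-examined by
# the trained classifier. Unknown terms are hard errors: extend this file for
# other MAF dialects instead of letting records drop silently.
impactful:
  - stop_gained
  - nonsense
  - missense
  - frameshift
  - splice_site
  - splice_acceptor
  - splice_donor
  - inframe_insertion
  - inframe_deletion
  - stop_lost
  - start_lost
non_impactful:
  - synonymous
  - 5_prime_UTR
  - 3_prime_UTR
  - intron
  - upstream
  - downstream
  - intergenic
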