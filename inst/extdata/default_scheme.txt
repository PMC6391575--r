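# Default slot scheme for miRNA mention recognition.
# Order is open class: 1-4 digits, up to two letters, an optional digit
# (covers numbering strings like 21, 181b, 16a1, 128c).
VERSION fig-default-1
SLOT Prefix
SLOT Precursor PARENT Prefix
  pre
  pri
SLOT Species PARENT Prefix
  hsa
  cel
SLOT miRNA
  mir
  mirna
  microrna
  micro rna
  lsy
SLOT Let PARENT miRNA
  let
  lin
SLOT Order OPEN ^[0-9]{1,4}[a-z]{0,2}[0-9]?$
SLOT Conj
  and
  or
SLOT Suffix
SLOT Hairpin PARENT Suffix
  3p
  5p
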