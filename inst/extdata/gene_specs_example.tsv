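# Example gene-specification table for NRA normalization.
# length_bp and copy_number should come from the organisms contributing the
# majority of best hits for each family; the values below are representative
# lengths for epsilonproteobacterial sulfur/nitrogen-cycle genes and are
# example inputs, not measurements.
family	length_bp	copy_number
sqr	1305	1
soxB	1734	1
soxY	432	1
dsrA	1332	1
dsrE	375	1
psrA	2286	1
aprA	1866	1
napA	2484	1
aclB	1164	1
rpoB	4107	1
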