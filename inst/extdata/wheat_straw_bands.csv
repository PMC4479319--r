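wavenumber,vibration,assignment
3380,O-H stretching of bonded and non-bonded hydroxyl groups,Included water; lignin
2920,Asymmetric C-H stretching,Aliphatic methylene
2850,Symmetric C-H stretching,Aliphatic methylene
1735,Un-conjugated C=O stretching,Xylan (hemicellulose)
1650,O-H bending / conjugated C-O stretching,Absorbed water; carboxylates
1600,Aromatic ring vibration / C=C skeletal vibration,Lignin
1510,Aromatic ring vibration,Lignin
1460,C-H deformation,Lignin; xylan
1429,C-H deformation / CH2 scissoring,Lignin; crystalline cellulose
1370,Symmetric C-H deformation,Crystalline cellulose; hemicellulose
1320,C-H vibration / CH2 wagging,"Cellulose, hemicellulose, lignin"
1240,C-O stretching,Xylan (hemicellulose)
1160,C-O-C asymmetric stretching,Crystalline cellulose; hemicellulose
1111,In-plane ring stretching,Crystalline cellulose
1053,C-O stretching,Crystalline cellulose; hemicellulose
898,C-O-C stretching,Amorphous cellulose
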