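{"tokens":["<pad>","<start>","<end>","<unk>","-",",","?","{","}","0","5","6","7","a","b","c","d","e","f","g","h","i","j","k","l","m","n","o","p","r","s","t","u","v","w","x","y","z","-",",","?","{","}","50","a","action","after","age","an","and","axillary","breast","can","ceus","circumscribed","classification","clip","contrast","disease","dynamic","enhanced","enhancement","here","high","human","in","index","injection","intense","irregular","is","judged","ki67","kinetics","lesion","look","low","lymph","margin","metastatic","microbubble","mild","node","nodes","non","of","on","or","out","over","pattern","perfusion","rapid","recognize","sample","showing","shows","slow","status","symptom","the","this","tumor","ultrasound","under","video","wash","with","you"]}
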