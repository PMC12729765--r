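{"pre":["{}, an action","{} this is an disease","{}, a video of symptom","{}, a contrast enhanced ultrasound video of a breast lesion","{}, axillary lymph node status on breast ceus","{} breast tumor with dynamic contrast enhancement"],"mid":["video classification of {}, a disease","the disease is {}, look here","Can you recognize {}? a Symptom of disease","a breast lesion showing {}, on contrast enhanced ultrasound","ceus perfusion pattern of {}, in a breast tumor","this ultrasound clip shows {}, after microbubble injection"],"post":["a video of action {}","a sample of disease {}","Human of {}","a ceus video of a {} breast lesion","axillary lymph nodes judged {}","wash in and wash out kinetics of a {} lesion"],"class_labels":["non-metastatic","metastatic"]}
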