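{"case_id":"case24815161","doc_type":"admission_record","text":"Record case24815161. Physical examination revealed disturbance of consciousness. History was significant for fever. Physical examination revealed poor feeding. Recurrent respiratory infection was noted on admission. Physical examination revealed cardiacm urmur. Physical examination revealed cyanosis. No dyspnea was noted. The patient denied diaphoresis. History was significant for fatigue. No digoxin was given. Echocardiographz was performed. The patient underwent chest x ray."}
{"case_id":"case24815161","doc_type":"imaging_report","text":"Report case24815161. The study showed atrial septal defect. Patetn ductus arteriosus was seen. Patent foramen ovale was seen. Imaging demonstrated mitral regurgitation. Imaging demonstrated left atrial enlargement. The lesion size of the ventricular septal defect was 1.8 cm. The ejection fraction of the left ventricular dysfunction was 54.5 %. The pressure gradient of the pulmonary valve stenosis was 25.3 mmHg. The ascending aorta diameter of the aortic dilatation was 27.2 mm."}
{"case_id":"case00573279","doc_type":"admission_record","text":"Record case00573279. There was no disturbance of consciousness. The patient denied feeding difficulty. History was significant for failure to thrive. Recurrent respiratory infection was noted on admission. The patient had lower limb edema. The patient had chest pain. Cardiac murmur was noted on admission. No cyanosis was noted. There was no dyspnea. Diaphoresis was noted on admission. History was significant for palpitations. History was significant for fatigue. The patient did not receive furosemide. The patient received captopril. The patient underwent chest x ray."}
{"case_id":"case00573279","doc_type":"imaging_report","text":"Report case00573279. The study showed atrial septal defect. There was no patent ductus arteriosus. There was no tricuspid regurgitation. Imaging demonstrated mitral regurgitation. The study showed pulmonary hypertension. There was no left atrial enlargement. Pericardial effusion was seen. No aortic coarctation was seen. The study showed right ventricular hypertrophy. The ejection fraction of the left ventricular dysfunction was 64.1 %. The ascending aorta diameter of the aortic dilatation was 22.6 mm."}
{"case_id":"case73106129","doc_type":"admission_record","text":"Record case73106129. History was significant for impaired consciousness. Physical examination revealed fever. No feeding difficulty was noted. The patient denied failure to thrive. Recurrent respiratory infection was noted on admission. There was no chest pain. Syncope was noted on admission. History was significant for hepatomegaly. The patient had wheezing. Cardiac murmur was noted on admission. History was significant for cyanosis. Shortness of breath was noted on admission. Physical examination revealed diaphoresis. History was significant for palpitations. Digoxin was given. The patient did not receive furosemide. Cardiac ultrasound was performed. No ecg was performed. No chest radiograph was performed."}
{"case_id":"case73106129","doc_type":"imaging_report","text":"Report case73106129. The study showed atrial septal defect. Patent ductus arteriosus was seen. The study showed patent foramen ovale. Imaging demonstrated tricuspid regurgitation. The study showed mitral regurgitation. No left atrial enlargement was seen. Aortic coarctation was seen. The study showed right ventricular hypertrophy. The ejection fraction of the left ventricular dysfunction was 61.9 %. The pressure gradient of the pulmonary valve stenosis was 74.3 mmHg."}
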